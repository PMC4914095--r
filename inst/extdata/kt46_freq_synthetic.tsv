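3b	A	C	G	U
A	0	0	99.75	0
C	0	0	0	0
G	0	0.19	0	0
U	0	0	0.06	0
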