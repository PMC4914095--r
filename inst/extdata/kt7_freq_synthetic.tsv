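3b	A	C	G	U
A	0	0	0.29	0
C	3.0	2.5	0	0.8
G	0	0.31	1.04	0
U	0	0	92.06	0
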