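3b	A	C	G	U
A	0	0	71.4	4.9
C	2.3	2.0	0	0
G	0	2.0	0	0
U	6.0	5.4	6.0	0
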