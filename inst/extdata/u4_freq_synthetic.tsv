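3b	A	C	G	U
A	6.0	4.8	0.2	7.1
C	0.4	0.3	0.5	0.2
G	0.5	62.6	0.2	4.5
U	0.5	1.0	0.4	10.8
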