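b	n	conformation	folds	n_n3	n_n1	provenance	notes
A	A	N3	no	1	0	figure (graphical, transcribed)
A	C	N3	no	1	0	figure (graphical, transcribed)
A	G	N3	yes	4	1	text	ribosomal HmKt-7 copy is N1 in situ (tertiary contacts + L24 binding); majority of independent structures N3
A	U	unknown	no	0	0	text	no variant structure obtained; Watson-Crick, so predicted non-folding
C	A	N1	yes	0	1	text
C	C	N1	yes	0	1	text
C	G	N3	no	1	0	figure (graphical, transcribed)	Watson-Crick: not folded by metal ions alone
C	U	N1	yes	0	1	figure (graphical, transcribed)
G	A	unknown	no	0	0	figure (graphical, transcribed)	empty cell
G	C	N3	no	3	0	text
G	G	N1	yes	0	1	text	breaks the 3b-purine-implies-N3 tendency
G	U	N3	no	1	0	figure (graphical, transcribed)
U	A	N1	no	0	1	figure (graphical, transcribed)
U	C	N1	no	0	1	figure (graphical, transcribed)
U	G	N1	yes	0	3	text	same conformation in riboswitch, ribosomal and protein-bound environments
U	U	N3	no	3	0	text
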