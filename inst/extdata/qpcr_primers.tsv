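gene_symbol	direction	sequence
CD27	F	GGCACTGTAACTCTGGTCTTC
CD27	R	ACTGACATAAGGTAAGTGGGTG
CSMD1	F	GAAACTCGATGTCTGGCTGG
CSMD1	R	CACTGCCATTAGTGAATCCG
USP44	F	GGTCAGGACGTAATAACCGAGAG
USP44	R	GCGGACAAGTCATAGATAAAGCAT
TIAL1	F	CCTAATCATCTTATTCAGCCTATCC
TIAL1	R	GCCTTCCTTTCGCCACTCT
MUC12	F	CAGCATACAAGCAATGACCCA
MUC12	R	GGACTCAAATCCCCAACAAAC
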