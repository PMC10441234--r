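transcript_id	gene_symbol	fold_change	regulation	p_value
ENST00000266557	CD27	3.270	Hyper	0.0009
ENST00000537824	CSMD1	4.559	Hyper	0.0020
ENST00000258499	USP44	0.001	Hypo	0.0000
ENST00000436547	TIAL1	0.023	Hypo	0.0004
ENST00000536621	MUC12	0.002	Hypo	0.0000
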