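term_id	gene_id	evidence
DOID:0000162	TP53	EXP
DOID:0000162	KRAS	EXP
DOID:0000162	TP53	TAS
DOID:0001816	KDR	IEA
DOID:0001816	TP53	EXP
DOID:0002256	COL2A1	EXP
DOID:0002256	COMP	TAS
DOID:0007566	TP53	IEA
DOID:0007566	EPCAM	EXP
DOID:0000001	BRCA1	EXP
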