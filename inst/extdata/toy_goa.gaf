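!gaf-version: 2.1
!generated-by: toy fixture
UniProtKB	P04637	TP53	enables	GO:0006915	PMID:1	EXP	-	P	tumor protein p53	-	protein	taxon:9606	20170201	UniProt	-	-
UniProtKB	P04637	TP53	enables	GO:0008283	PMID:2	TAS	-	P	tumor protein p53	-	protein	taxon:9606	20170201	UniProt	-	-
UniProtKB	P35968	KDR	enables	GO:0006915	PMID:3	IEA	-	P	kinase insert domain receptor	-	protein	taxon:9606	20170201	UniProt	-	-
UniProtKB	P38398	BRCA1	enables	GO:0006915	PMID:4	EXP	-	P	BRCA1 DNA repair associated	-	protein	taxon:9606	20170201	UniProt	-	-
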