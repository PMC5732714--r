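format-version: 1.2
ontology: toy-disease-ontology

[Term]
id: DOID:0000001
name: disease

[Term]
id: DOID:0000162
name: cancer
alt_id: DOID:9999162
synonym: "malignant tumor" EXACT []
synonym: "malignancy" RELATED []
is_a: DOID:0000001 ! disease

[Term]
id: DOID:0001816
name: angiosarcoma
is_a: DOID:0000162 ! cancer

[Term]
id: DOID:0002256
name: osteochondrodysplasia
is_a: DOID:0000001 ! disease

[Term]
id: DOID:0007566
name: eccrine porocarcinoma
synonym: "porocarcinoma" EXACT []
is_a: DOID:0000162 ! cancer
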