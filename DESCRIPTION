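Package: cooclink
Title: Sentence-Level Co-Occurrence Associations Between Biomedical Ontology Terms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts sentence-level co-occurrence relationships between
    biomedical ontology terms (Gene Ontology, Disease Ontology) from
    literature abstracts and scores the strength of each term pair with the
    relationship-scaled score (RSS) and the Normalized MEDLINE Distance
    (NMD). Provides OBO and annotation-file readers, a rule-based sentence
    segmenter, a dictionary matcher over ontology names and synonyms,
    co-occurrence indexing, score validation against ontology-structure
    (Wang) and gene-annotation similarity, and construction of thresholded
    term-association networks with degree, giant-component and power-law
    diagnostics. A seeded synthetic-data generator produces toy ontologies,
    annotations and corpora with planted associations so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table (>= 1.14.0),
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
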