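Package: Cellulotype
Title: Genome-Centric Genotyping of Putative Cellulolytic Anaerobes from
    CAZyme Annotations
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies and prioritizes putative cellulolytic anaerobes from
    per-gene CAZy module annotations. Extracts protein sequences from GenBank
    flat files, ingests dbCAN-style HMM search tables, types carbohydrate-active
    genes by their module architecture (cellulosome scaffoldins, dockerin-borne
    catalytic components, SLH-cCBM adhesion genes, cellulose-binding and free
    cellulases), classifies genomes into six cellulolytic genotype groups via a
    decision tree over gene-type presence, computes module co-occurrence
    frequencies across a genome collection, and renders gene-architecture
    diagrams. Ships a synthetic-corpus generator with ground-truth labels so
    the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    pheatmap
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Annotation, FunctionalPrediction, Classification, Microbiome
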