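Package: cpistack
Title: Chemical-Protein Interaction Extraction with Stacked Generalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts chemical-protein interactions (CPIs) from
    entity-annotated biomedical abstracts in the ChemProt tab-separated
    format. Candidate chemical-protein pairs and pair-plus-interaction-word
    triplets are built per sentence, featurized with semantic-pattern and
    shortest-dependency-path features, and classified into CPR interaction
    groups (3: up-regulator, 4: down-regulator, 5: agonist, 6: antagonist,
    9: substrate) by a three-stage stacked-generalization model built from
    out-of-fold meta-features. Includes corpus readers and writers,
    a pluggable dependency-parser adapter, micro-averaged
    precision/recall/F1 evaluation with per-class confusion matrices, and
    a deterministic synthetic-corpus generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ranger,
    xgboost,
    nnet,
    MASS,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
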