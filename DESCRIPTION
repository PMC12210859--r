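Package: esomicro
Title: Stage-Resolved Analysis of Esophageal Bacterial and Fungal Communities
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for amplicon feature tables (16S rRNA and ITS)
    sampled across esophageal disease stages: feature-table input/output and
    filtering, Hill-number alpha diversity with rank-based group contrasts,
    Hellinger/Bray-Curtis beta diversity with PCoA, PERMANOVA and ANOSIM,
    Type-I Taylor power-law extension fits of community spatial heterogeneity
    with permutation contrasts, permutation null models for shared-species
    counts, effect-size (LEfSe-style) biomarker screening, SparCC
    compositional co-occurrence networks with MCODE-style core detection,
    network backbones and a cross-network functional-group procedure, marker
    ROC analysis, clinical contingency-table statistics, and a seeded
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    igraph,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
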