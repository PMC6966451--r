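Package: tadprog
Title: Consensus TAD Maps, CNV Enrichment, and TAD-Based Survival Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links the three-dimensional organization of the genome to cancer
    prognosis. Builds a consensus map of topologically associating domains
    (TADs) from multiple tissue-specific TAD maps using expression-derived
    tissue weights and windowed conservation/boundary scores; tests consensus
    TADs for enrichment or depletion of somatic copy-number variants (CNVs)
    against size-matched random genomic regions; fits repeated LASSO Cox
    proportional-hazards models on TAD-level CNV presence features and
    aggregates them into a final prognostic model with risk stratification;
    classifies normal TADs as constitutive, perturbed, split, or fused
    relative to a cancer consensus map and computes binned meta-profiles.
    Includes a synthetic-cohort generator emulating multi-tissue TAD maps,
    clade-structured expression counts, patient CNV segments with spiked
    recurrence, and proportional-hazards survival times, so the whole
    pipeline is testable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    glmnet,
    data.table,
    S4Vectors,
    IRanges,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
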