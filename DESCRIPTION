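Package: macpol
Title: Boolean Modelling of Macrophage Polarization and Nurse-Like Cell
    Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A synchronous Boolean model of monocyte-to-macrophage
    polarization covering the M0, M1 (pro-inflammatory), M2
    (anti-inflammatory) and nurse-like cell (NLC, the tumour-associated
    macrophage of chronic lymphocytic leukaemia) phenotypes.  Ships a
    40-node gene-regulatory network (10 extracellular signals, 30
    intracellular components), an exact fixed-point attractor solver based
    on constant propagation and feedback-vertex-set enumeration with an
    exhaustive state-transition-graph oracle, supervised phenotype
    classification from marker signatures, Jaccard-Needham attractor
    similarity with hierarchical density-based clustering, and in-silico
    stimulus, knock-out and constitutive-activation experiments.  Includes
    seeded generators for random Boolean networks and planted-cluster
    binary datasets so every pipeline stage is testable without external
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
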