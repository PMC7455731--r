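Package: ccsatlas
Title: Unified Collision Cross-Section Atlases, CCS Prediction, and
    Multi-Dimensional Metabolite Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for ion mobility-mass spectrometry metabolomics:
    standardization of heterogeneous experimental collision cross-section
    (CCS) records from multiple laboratories and instrument platforms into a
    unified database with confidence levels; machine-learning CCS prediction
    by support vector regression on molecular descriptors, with a
    representative structure similarity (RSS) score that estimates prediction
    reliability from fingerprint similarity to the training set; and
    multi-dimensional metabolite annotation combining m/z, CCS and MS/MS
    matching with trapezoidal CCS scoring, reverse dot-product spectral
    similarity and weighted score integration. A deterministic simulator
    generates compound libraries, multi-laboratory CCS records with injected
    faults, and toy fragment spectra so the whole pipeline can be exercised
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    e1071,
    glmnet,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
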