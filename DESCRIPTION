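Package: cllrs
Title: Boolean Network Modeling of CLL Transformation to Richter Syndrome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synchronous Boolean network machinery for studying the
    transformation of chronic lymphocytic leukemia (CLL) into Richter
    syndrome (RS). Provides rule-file parsing in the common
    "targets, factors" dialect, attractor detection with exhaustive and
    sampling-based basin estimation, phenotype classification of attractor
    landscapes (anergy, proliferation, apoptosis, cell-cycle alert,
    quiescence), exhaustive in-silico knockout/knockin screening for tumor
    drivers and drug targets, bit-flip robustness testing against matched
    random N-K networks, discrete power-law degree analysis, graded two-input
    input-output grids, deterministic trajectory tracing with per-step flip
    attribution, step-function (BASC-A style) expression binarization with a
    model/data concordance pipeline, and generators for synthetic networks
    and sparse single-cell-like expression matrices with ground truth.
    Ships a literature-motivated reconstruction of a CLL/RS signaling
    network together with named simulation scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pROC
Config/testthat/edition: 3
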