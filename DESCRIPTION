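Package: tfhierarchy
Title: Hierarchy and Conservation Analysis of Cell-Type Transcription
    Factor Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for profiling collections of directed transcription
    factor (TF) regulatory networks across cell types: three-layer
    (top/core/bottom) hierarchy decomposition by vertex sort, local and
    global reaching centrality, housekeeping versus cell-type-specific
    interaction calculus with leave-k-out validation, cell-type
    classification from local TF wiring (binary target features, PCA,
    Ward clustering, Rand index), hypergeometric layer enrichment,
    tissue-expression relative entropy, and detection of regulatory
    complex-target modules as maximal bicliques.  Includes seeded
    synthetic-data generators with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
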