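Package: tfbait
Title: Transcription Factor Discovery by Adaptive Sparse Canonical
    Correlation Baiting
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate transcription factors (TFs) for a
    biological process from genome-wide expression data by baiting them
    with clusters of known positive target genes via adaptive sparse
    canonical correlation analysis (ASCCA).  Hooked TF sets are retained
    by an enrichment test against known positive TFs and pooled into a
    recurrence-frequency ranking.  An Intersection-of-Coexpression (ICE)
    baseline based on Spearman link counts is included for comparison,
    together with a seeded synthetic-data generator that plants
    TF-to-target regulatory modules for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
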