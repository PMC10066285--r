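Package: rbpscreen
Title: Design and Analysis of RNAcompete-Style RNA-Binding Specificity Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for designed-pool RNA-binding specificity screens: order-n
    de Bruijn oligonucleotide pool generation with balanced Set A/B splits and
    per-k-mer coverage guarantees, probe-intensity normalization and 7-mer
    Z-score computation, motif construction from top-scoring 7-mers with
    information content and motif-motif comparison, an L1-regularized logistic
    pass/fail/uncertain experiment classifier, a synthetic probe-intensity
    simulator with planted specificity signals for end-to-end testing, and
    eCLIP peak 5-mer profiling with correlation clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    glmnet,
    jsonlite,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    ape,
    graphics,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
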