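Package: snspmf
Title: Weighted Sparse Semi-Nonnegative Matrix Factorization for Multi-Tissue eQTL Effects
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decomposes matrices of multi-tissue eQTL effect sizes into a
    nonnegative tissue-factor matrix and a sparse real-valued loading matrix by
    weighted, L1-penalized, semi-nonnegative matrix factorization fit with
    alternating least squares. Includes stability-based hyper-parameter
    selection via consensus matrices and cophenetic correlation, per-eQTL
    weighted-regression assignment to factors with FDR control and
    discrepancy filtering, threshold-based heuristic baselines, a simulation
    framework with recovery metrics, and downstream enrichment statistics
    (matched background sampling, interval-overlap Fisher tests,
    random-effects odds-ratio combination, and allele-specific binding tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    igraph,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: GeneExpression, SNP, DimensionReduction, Regression, Software
RoxygenNote: 7.3.3
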