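Package: cresignal
Title: Sequence-Based Prediction of Regulatory-Element Peaks from
    Functional-Genomics Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures how well DNA sequence alone predicts peaks called from
    functional-genomics assays (STARR-seq, chromatin accessibility, histone
    ChIP-seq). Provides summit-centered window extraction from narrowPeak
    files, exclusion-aware sampling of matched genomic control regions,
    6-8-mer count features with an ensemble of L2-regularized logistic
    regressions fit by stochastic gradient descent, chromosome-arm holdout
    cross-validation with ROC AUC evaluation, cross-assay transfer of
    enhancer models, and the statistics used to compare model predictions
    with dual-luciferase reporter measurements (exact binomial, one-sample t
    with Bonferroni control, Mann-Whitney, Pearson correlation). A synthetic
    genome simulator with planted motif signal makes every stage testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
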