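Package: lonestar
Title: Sparse Combined L1/L2-Norm Support Vector Classification for
    Few-Sample Biomarker Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects small predictive biomarker panels from expression
    matrices with many more features than samples. Fits a linear support
    vector classifier whose regularizer is a convex combination of the
    l1-norm and the un-squared l2-norm, which yields exactly sparse weight
    vectors while keeping correlated features together. Wraps the solver in
    stability selection over random balanced subsamples, recursive feature
    elimination, and best-classifier averaging. Includes per-feature
    normalization, an optional two-sample t-test prefilter, serialization
    of fitted classifiers to JSON, prediction on independent cohorts, and
    evaluation by contingency-table metrics with Fisher and Barnard exact
    tests. A synthetic cohort generator with planted sparse signals and
    block-correlated features supports calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
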