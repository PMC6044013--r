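Package: batchfx
Title: Empirical Bayes Batch Effect Adjustment and Moment-Based Diagnostics
    for Expression Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Location-scale batch effect adjustment for gene-by-sample
    matrices of log-scale expression values via parametric empirical Bayes
    shrinkage (the ComBat model family), including a mean-only variant that
    leaves within-batch variances untouched and a reference-batch variant
    that returns one designated batch unchanged and adjusts all other
    batches to its mean and variance profile. Also provides moment-based
    batch-effect diagnostics (sample-level and gene-level tests of mean,
    variance, skewness and kurtosis with standard and robust F statistics),
    synthetic-data generators for a two-batch pathway-signature study and a
    two-batch differential-expression study, and evaluation harnesses
    (k-means signature recovery, type-I error and power).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    sva,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
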