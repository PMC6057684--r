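Package: glucotyper
Title: Glycemic Signature Classification from Continuous Glucose Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies continuous glucose monitoring (CGM) time series into
    low, moderate, and severe glycemic-signature classes. Sliding windows of
    a CGM trace are compared with a complexity-invariant dynamic time warping
    (CID-DTW) dissimilarity restricted to a Sakoe-Chiba band, clustered by
    spectral clustering with eigengap model selection, and new windows or
    standardized-meal responses are classified out-of-sample by projection
    onto the trained spectral embedding. Also provides the standard suite of
    glycemic-variability metrics (MAGE by turning-point elimination, J index,
    MODD, distance traveled, coefficient of variation, time in glycemic
    ranges), ADA-threshold diagnostic summaries, cluster-quality metrics for
    window-size and distance-metric optimization, and a seeded synthetic CGM
    cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
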