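Package: dynfc
Title: Static and Dynamic Functional Connectivity States from Resting-State BOLD Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for resting-state functional-connectivity
    analysis of multi-subject BOLD time series: framewise-displacement quality
    control, scaled group spatial ICA with ICASSO stability and
    back-reconstruction, intrinsic-connectivity-network selection by spectral
    criteria, time-course post-processing (polynomial detrend, spline despike,
    zero-phase Butterworth low-pass), static Fisher-z connectivity, tapered
    sliding-window connectivity with L1-regularized (graphical lasso)
    covariance estimation, deep clustering of connectivity windows (autoencoder
    dimensionality reduction followed by exemplar-initialized k-means with
    elbow selection of the state count), state temporal metrics (dwell time,
    fractional occupancy), and case-control statistics (covariate-residualized
    t-tests with false-discovery-rate correction, ANCOVA). Includes a
    synthetic-cohort generator with planted covariance states switching under
    a hidden Markov sequence, so every stage can be validated against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
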