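Package: minmaxpat
Title: Local Min/Max-Pattern Features and Self-Organized Classification for Physiological Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature engineering and classification toolkit for one-dimensional
    physiological time series (e.g., single-lead ECG). Implements the MinMaxPat
    descriptor (a 256-bin histogram of base-16 codes built from the positions of
    the minimum and maximum in overlapping 16-sample windows), neighborhood
    component analysis (NCA) feature weighting with cumulative-weight iterative
    selection (CWINCA), and a self-organized ensemble k-nearest-neighbor
    classifier (tkNN) that pools 90 weighted-kNN parameterizations with 88
    iterative-majority-voting aggregates. Includes stratified 10-fold and
    leave-one-record-out cross-validation drivers, confusion-matrix metrics,
    and a synthetic multi-record signal generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
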