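Package: imusleep
Title: Infant Sleep Staging and Sleep Depth Trends from Waist-Worn IMU Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing overnight recordings from a waist-worn
    inertial measurement unit (13 Hz triaxial accelerometer and gyroscope)
    in infants. Extracts per-30-s-epoch movement activity, four
    gyroscope-derived respiration parameters and a gravity-based posture
    code, identically in batch and streaming mode; trains a two-layer
    bidirectional gated recurrent unit (GRU) classifier for three
    vigilance states (Wake, N1/REM, N2/N3) with leave-one-subject-out
    cross-validation; and converts per-epoch class probabilities into a
    continuous Sleep Depth Trend with a confidence band. Includes a
    seeded semi-Markov simulator of infant overnight IMU streams with
    ground-truth hypnograms so the full pipeline can be exercised without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
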