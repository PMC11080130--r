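Package: semgscreen
Title: Sarcopenia Screening from Forearm Surface Electromyography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation, preprocessing, feature extraction, statistics and
    classification tools for surface electromyography (sEMG) based sarcopenia
    screening. Provides a motor-unit-pool simulator of multichannel forearm
    sEMG with healthy and sarcopenic contraction physiology, zero-phase
    notch and band-pass filtering with automated stationary-segment
    selection, the Hudgins time-domain feature set together with Morlet
    continuous-wavelet-transform power, wavelet entropy and coefficient-
    density kurtosis, maximal-voluntary-contraction feature normalization,
    nonparametric group comparisons with exact small-sample branches, the
    AWGS 2019 screening rule, a sensitivity-weighted soft-voting classifier
    (linear support vector machine, random forest, gradient boosting) under
    leakage-free subject-level cross-validation, and permutation-sampling
    Shapley estimates of per-feature impact.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    e1071,
    ranger,
    xgboost,
    data.table,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
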