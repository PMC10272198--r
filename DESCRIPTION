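Package: serafir
Title: Chemometric Classification of Serum ATR-FTIR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native chemometrics pipeline for case-control
    classification of attenuated total reflection Fourier-transform infrared
    (ATR-FTIR) biofluid spectra. Implements Savitzky-Golay smoothing,
    automatic-weighted least squares baseline correction, biofingerprint
    truncation, replicate averaging and train-mean centering; Kennard-Stone
    train/test splitting and venetian-blinds cross-validation; principal
    component analysis and successive projections algorithm (SPA) variable
    selection scored by a Mahalanobis cost; non-Bayesian linear and quadratic
    discriminant scores and a soft-margin RBF support vector machine solved by
    sequential minimal optimisation; confusion-based figures of merit
    (accuracy, sensitivity, specificity, F-score, G-score) and prominence-based
    loading-peak identification. Ships a seeded synthetic-cohort generator with
    class-discriminative absorption bands so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    e1071,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
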