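Package: vitalcast
Title: High-Rate Early Warning Scores and Short-Horizon Vital-Sign
    Forecasting from Continuous Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for continuously monitored vital signs of
    hospitalised patients. Provides a seeded synthetic cohort generator for
    multichannel 1 Hz recordings (heart rate, respiration rate, blood
    pressures, oxygen saturation), per-minute zero-phase Butterworth
    denoising, early-warning-score (EWS) component scoring against
    hospital threshold tables, overlapping-window statistical feature
    extraction, a localized k-nearest-neighbour least-squares
    support-vector-machine (kNN-LS-SVM) regressor for predicting windowed
    vital-sign statistics one to three hours ahead, and
    leave-one-instance-out evaluation against a naive persistence baseline
    with absolute error, MAPE, EWS-error histograms and paired t-tests.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
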