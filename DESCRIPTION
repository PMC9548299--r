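Package: ventrisk
Title: Continuous-Monitoring Risk Models for Respiratory Failure Leading
    to Emergent Intubation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for validating continuous cardiorespiratory-monitoring
    risk models of respiratory failure leading to emergent intubation in
    ICU patients. Provides a synthetic ICU cohort generator with ground
    truth, reconstruction of mechanical-ventilation epochs from ventilator
    respiratory-rate flowsheet entries, extraction of vital-sign and
    cardiac-dynamics predictors (windowed statistics, cross-correlations,
    SDNN, coefficient of sample entropy, detrended fluctuation analysis)
    in overlapping 30-minute windows, logistic risk models with linear or
    restricted-cubic-spline bases emitting relative-risk series, and an
    evaluation suite: event-aligned risk trajectories, signed-rank lag
    tests, window-dependent AUC with admission-level bootstrap, and
    decile calibration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
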