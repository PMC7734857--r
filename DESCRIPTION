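Package: hrvdistf
Title: Sliding-Window Heart Rate Variability Distance Features for ICU
    Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting intensive-care outcome from continuous
    heart rate variability (HRV) monitoring. Computes the standard time
    domain, frequency domain (Welch spectral) and Poincare HRV parameters
    over consecutive 30-minute epochs of an RR-interval series, derives
    sliding-window Euclidean-distance features that summarise the
    fluctuation of each parameter across consecutive epochs, and selects
    predictive feature subsets for a logistic outcome classifier with a
    genetic algorithm whose fitness is the cross-validated Youden index
    under repeated, patient-grouped five-fold cross-validation. Includes a
    synthetic cohort generator with outcome-dependent autonomic spectral
    structure so the whole pipeline can be exercised and tested without
    access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
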