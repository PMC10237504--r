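Package: metsrisk
Title: Metabolic Syndrome Risk Modelling with Criterion-Scaled Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for noninvasive metabolic syndrome (MetS)
    prediction. Generates criterion-consistent synthetic health-checkup
    cohorts, diagnoses MetS under the revised NCEP ATP III criteria with
    Korean waist cutoffs, computes elliot-sigmoid criterion-scaled
    anthropometric features and classical body-shape indices, runs a
    repeated-split undersampled model-selection protocol (importance
    filtering, recursive feature elimination, ranked-prefix subset search),
    calibrates predicted probabilities (Platt scaling, isotonic regression,
    undersampling bias correction with a derived decision threshold),
    assesses calibration by Brier score and Spiegelhalter's z-test, and
    converts a depth-limited decision tree over the scaled waist and blood
    pressure features into a two-dimensional calibrated risk map.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart,
    ranger,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    ggplot2
Config/testthat/edition: 3
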