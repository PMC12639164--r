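Package: tbptriage
Title: Simulation and Evaluation of Automated Skin-Lesion Triage from 3D
    Total-Body Photography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study machine-learning triage of cancer-suspicious skin
    lesions detected on 3D total-body photography (TBP). Provides a synthetic
    multi-center cohort generator that emulates per-patient lesion tiles and
    vendor-style appearance measurements at realistic (~0.1%) malignancy
    prevalence; pixel-based lesion segmentation and CIELAB morphology
    measurements from 15x15 mm tiles; patient-contextual ("ugly duckling")
    feature engineering; a multivariable logistic baseline and a
    gradient-boosted multi-modal risk model fit under a ten-variant feature
    ablation design with patient-grouped cross-validation; and triage-oriented
    evaluation statistics: partial AUC above a sensitivity floor, number
    needed to triage at fixed sensitivity, patient-weighted top-k sensitivity,
    per-patient percentile placement of malignancies, DeLong comparison of
    correlated AUCs, and rank-aggregated risk-feature association.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    utils,
    xgboost,
    EBImage,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
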