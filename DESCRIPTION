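Package: pareadmit
Title: Activity-Based 30-Day Hospital Readmission Prediction from Wrist
    Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to predict 30-day hospital readmission of COPD patients
    from continuous physical-activity data recorded by a wrist-worn
    tri-axial accelerometer. Implements activity-based feature extraction
    (per-epoch resultant-acceleration statistics, minute-level Activity
    Index, day-pair Regularity Index, daily Quality of Activity, and a
    16-hour wear-validity rule), sliding 7-day window construction with
    30-day-lookahead labelling, a from-scratch logistic-regression
    classifier trained by stochastic gradient descent with blocked 10-fold
    cross-validation, and dual prediction-based / event-based evaluation
    statistics. A synthetic wearable-cohort generator with circadian
    structure, activity bouts, non-wear gaps and pre-readmission activity
    decline makes the full pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
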