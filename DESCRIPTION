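Package: journeydrop
Title: User-Journey Feature Engineering and Dropout Prediction for
    Digital Health Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Transforms long-format touchpoint logs from digital health
    interventions (self-report diaries, questionnaires, system events)
    into model-ready feature matrices, engineers rolling-window and
    theory-driven features, handles missing data by threshold deletion
    and median/mode or mixed-type k-nearest-neighbour imputation,
    predicts participant dropout at successive intervention timepoints
    with cross-validated classifiers, and attributes predictions to
    features via Shapley values. Ships a seeded cohort simulator that
    emulates a multi-core gated intervention with a known dropout
    mechanism for end-to-end and signal-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    glmnet,
    e1071,
    xgboost,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
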