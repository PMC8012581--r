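Package: neoworry
Title: Continuous Mortality-Risk Prediction for Very Preterm Infants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A continuous neonatal mortality-risk pipeline for very preterm
    (< 32 weeks) infants: rolling-window feature extraction from 1-Hz
    bedside vital signs (heart rate, respiratory rate, pulse oximetry,
    blood pressure), 6-hour "worry" labeling relative to death time,
    balanced random-forest classification with infant-level
    cross-validation, CRIB-II and static-only logistic baselines, and
    per-timepoint plus per-infant ROC evaluation. Includes a calibrated
    synthetic NICU cohort and vital-sign simulator with configurable
    artifacts and a pre-mortem decompensation signature, standing in for
    clinical archives that cannot be shared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    glmnet,
    jsonlite,
    ranger,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
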