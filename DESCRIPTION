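Package: emarisk
Title: Ecological Momentary Assessment Features and Suicidal Ideation Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates ecological momentary assessment (EMA) cohorts with a known
    signal structure (AR(1) latent mood discretized to six ordinal items, stressful
    event checklists with culture-wave rate shifts, logistic outcome models whose
    mood effects decay with follow-up horizon while event effects persist), reads
    and day-aggregates long-format EMA survey data under a survey-level missingness
    rule, extracts 60 intensive-longitudinal features (mean, SD, slope, maximum
    change and probability of acute change per series, plus per-category stressful
    event frequencies), and evaluates gradient-boosted tree classifiers of
    follow-up suicidal ideation under repeated stratified cross-validation with
    AUC, sensitivity, specificity, positive predictive value, split-count feature
    importance, predictor-set comparisons, incremental-day learning curves and
    per-wave analyses with Welch t tests and Benjamini-Hochberg adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
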