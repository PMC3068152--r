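Package: profscore
Title: Gene Profile Score Classification for qPCR Biomarker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating multi-gene qPCR diagnostic panels with a
    binary gene-profile scoring metric. Computes delta-Ct and relative
    quantities (2^-ddCt), builds empirical ROC curves over all observed
    cut-offs, calibrates per-gene thresholds at a fixed false-positive rate,
    binarizes samples into gene profiles whose digit sum is the profile
    score, calibrates and applies a score-threshold classifier, and
    evaluates predictions with confusion matrices, per-gene accuracies,
    Welch t-tests and cross-dataset correlation. Includes a synthetic
    case/control panel generator (log2-normal expression shifts with
    missing-at-random entries) so the whole workflow is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
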