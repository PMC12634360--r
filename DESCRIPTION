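Package: ddss
Title: Surgeon-Specific Difficulty Assessment for Third-Molar Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decoupling-prediction workflow for assessing the operative
    difficulty of impacted mandibular third-molar extraction on a
    per-surgeon basis. Fits Lasso regularization paths of normalized
    operative duration on ordinal surgical indicators, extracts
    feature-activation-order preference sequences as surgeon signatures,
    clusters surgeons into experience groups by token-level Levenshtein
    distance with agglomerative linkage, trains per-group difficulty
    classifiers (SVM-RBF, random forest, gradient boosting), and derives
    monthly learning-curve trajectories of difficulty factors. Includes a
    synthetic clinic generator that emulates the categorical indicator
    marginals and per-surgeon duration profiles the method assumes, with
    planted experience groups for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    glmnet,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
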