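Package: tinvmark
Title: Time-Invariant Gene-Expression Biomarkers for Non-Genotoxic
    Hepatocarcinogen Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers gene-expression biomarkers of non-genotoxic
    hepatocarcinogens (NGHCs) that keep a constant modulation direction
    across exposure durations and microarray datasets. Implements
    per-chemical log2 expression profiling against controls, t-test plus
    fold-change differential-expression calls between NGHC and
    non-hepatocarcinogen chemical groups, cross-dataset consensus
    intersection, cross-exposure direction checks yielding time-invariant
    biomarker sets, leave-one-chemical-out cross-validated classifier
    evaluation (decision tree, bagging, boosting, k-nearest neighbour,
    naive Bayes, support vector machine, random forest) with
    performance-stability metrics (median AUC, IQR, coefficients of
    variation across datasets and exposures), cross-dataset external
    validation, and hypergeometric over-representation analysis with
    Bonferroni correction. A synthetic multi-dataset generator with
    planted time-invariant and time-variant signature genes makes the
    whole pipeline testable without external archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rpart,
    randomForest,
    e1071,
    class,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
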