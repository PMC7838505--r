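Package: contranet
Title: Contralesional Functional Network Analysis for Glioma Grade Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds resting-state functional connectomes from parcellated node
    time series (detrending, Friston-24 nuisance regression, band-pass
    filtering, Fisher-Z Pearson correlation), derives sparsity-integrated
    graph-topology features (clustering, path length, efficiency, small-world
    indices against degree-preserving null networks, nodal centralities),
    selects grade-discriminative features by repeated inner cross-validated
    ROC/AUC screening with one-sided confidence-interval thresholding and
    frequency ranking, and classifies tumor grade with SMOTE-balanced
    ridge-penalized multivariate logistic regression evaluated by stratified
    outer cross-validation, including cross-hemisphere validation. A synthetic
    cohort generator with planted covariance effects makes every stage testable
    without patient data.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    jsonlite,
    pracma,
    withr,
    zoo,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
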