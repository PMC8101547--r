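Package: spyctree
Title: Semi-Supervised Oblique Predictive Clustering Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Learns oblique predictive clustering trees from partially
    labeled tabular data. Split hyperplanes are optimized jointly over
    feature and target impurity, so unlabeled examples inform tree
    construction through the cluster assumption. Supports single-target
    and multi-target regression, binary, multi-class, multi-label and
    hierarchical multi-label classification, with an SVM-based and a
    gradient-based split learner, bagging ensembles, hyperplane-weight
    feature importances, supervision-degree selection by internal
    cross-validation, evaluation metrics (R-squared, F1, weighted label
    ranking average precision), a synthetic benchmark generator and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
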