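Package: nrmstack
Title: Neighbor-Recommender and Stacked Ensemble Models for Drug
    Combination Prediction
Version: 0.1.0
Authors@R:
    person("Combination", "Modelling Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Similarity-based prediction of synergistic drug pairs.
    Computes per-feature Tanimoto similarity matrices from set-valued drug
    annotation profiles (targets, indications, expression signatures,
    modules), scores candidate pairs with the neighbor recommender method
    on a known-combination network, assesses and selects informative
    feature channels (Welch t-test, signed two-sample Kolmogorov-Smirnov
    statistic, random-forest Gini importance), stacks the per-channel base
    predictors with a logistic meta-classifier, and evaluates everything
    with an imbalance-aware cross-validation harness (negative
    downsampling, link masking, repeated sampling, AUROC, AUPR, recall,
    precision, F1). Includes a synthetic-data generator with planted
    cluster structure and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
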