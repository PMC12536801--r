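Package: sporecast
Title: Predict Sporulation Potential of Bacterial Genomes from Gene Content
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the sporulation potential of Firmicutes genomes and
    metagenome-assembled genomes (MAGs) from the presence or absence of 160
    sporulation-associated genes. Parses eggNOG-mapper style functional
    annotation tables into binary feature matrices, trains and tunes random
    forest, RBF support vector machine, gradient boosting and neural network
    classifiers under stratified cross-validation, and combines the random
    forest and support vector machine into a stacked ensemble whose
    meta-classifier consumes leakage-free out-of-fold probabilities.
    Companion analyses include bootstrap performance evaluation with
    percentile confidence intervals, sampling-based Shapley attribution with
    a dual-model positive-consensus gene rule, core-gene extraction, and
    ordination plus multivariate dispersion analysis of presence/absence
    profiles with permutation ANOVA. A synthetic-data generator emulating a
    balanced labeled cohort with stage-block gene correlation and
    genome-incompleteness dropout makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    kernlab,
    nnet,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
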