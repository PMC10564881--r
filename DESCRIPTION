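Package: evoselect
Title: Evolutionary Joint Feature Selection and Hyperparameter Tuning with a BIC Fitness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An evolutionary meta-learner that jointly selects predictor subsets and
    tunes hyperparameters for three classifier families (elastic-net logistic
    regression, gradient-boosted trees, and a multilayer perceptron) against a
    Bayes Information Criterion fitness evaluated by stratified cross-validation.
    Includes the surrounding tabular pipeline for multidomain cohort studies:
    missingness filtering, outlier trimming, masked non-negative matrix
    factorization imputation, feature agglomeration, scaling and normalizing
    transforms, symptom-count target construction, SMOTE-ENN rebalancing,
    static and sliding-window dynamic functional connectivity metrics, held-out
    evaluation, and permutation/Shapley model explanation. A synthetic-cohort
    generator with planted signal supports end-to-end testing without access to
    restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    glmnet,
    generics,
    jsonlite,
    nortest,
    rlang,
    stats,
    tibble,
    utils,
    xgboost
Suggests:
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
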