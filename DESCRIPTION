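Package: methyldx
Title: Two-Stage CpG Site Screening and Gated-Residual Transformer
    Diagnosis from DNA Methylation Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens Illumina 450K-style DNA methylation beta-value
    matrices for CpG sites that are tissue-specific (chi-square
    contingency test over binned beta values in healthy samples) and
    disease-specific (per-tissue ridge-regularised logistic regression
    with coefficient-magnitude ranking), then trains a Transformer
    encoder with a sigmoid-gated dynamic residual layer to classify
    healthy versus disease samples from the selected sites. Includes a
    synthetic multi-tissue cohort generator with planted
    tissue-specific and disease-specific sites, stratified k-fold
    cross-validation with accuracy/recall/F1 and ROC/AUC, classical
    baseline models for comparison, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    class,
    e1071,
    optparse,
    randomForest,
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
RoxygenNote: 7.3.3
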