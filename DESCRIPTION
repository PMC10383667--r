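Package: ibdsig
Title: Monte Carlo Gene-Signature Discovery for Inflammatory Bowel
    Disease Expression Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers small gene signatures that separate inflammatory
    bowel disease (IBD) patients from controls, and Crohn's disease from
    ulcerative colitis, in labeled bulk expression matrices. The pipeline
    screens genes by point-biserial correlation with the class label,
    runs a Monte Carlo random subset-reduction search over a suite of 23
    classification algorithms with stratified k-fold cross-validation,
    sweeps multilayer perceptron depth as a neural-network baseline, and
    offers an L1-penalized logistic regression arm for comparison. A
    synthetic expression-study generator with planted informative genes
    provides ground truth for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    class,
    rpart,
    e1071,
    randomForest,
    xgboost,
    glmnet,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
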