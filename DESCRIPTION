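Package: cccf
Title: Consensus Classification of High-Risk Neutrophils and Multi-Model
    Prediction of Hemorrhage Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A peripheral-blood transcriptomic pipeline for intracerebral
    hemorrhage (ICH) risk in hypertensive patients. Implements signature
    extraction from single-cell differential expression, a cellular
    classification consensus framework (CCCF) that binarizes many per-cell
    gene-set scores at their medians and calls high-risk and low-risk
    neutrophils by unanimity, a deterministic pseudotime axis with
    Pearson-correlation gene selection, and a multi-model machine-learning
    integration framework that enumerates feature-selector and classifier
    combinations and ranks them by mean test/validation AUC. Ships a
    negative-binomial single-cell simulator and a Gaussian two-cohort bulk
    simulator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    class,
    e1071,
    glmnet,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
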