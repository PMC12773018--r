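Package: peptidev
Title: Leakage-Aware Multi-Property Prediction for Therapeutic Peptides
Version: 0.1.0
Authors@R:
    person("Peptidev", "Maintainers", email = "maintainers@peptidev.dev",
           role = c("aut", "cre"))
Description: A framework for predicting developability properties of
    therapeutic peptides in two input modalities (amino-acid sequences and
    SMILES strings): per-property datasets with validated records,
    similarity-aware clustering and leakage-proof cluster-level
    train/validation splitting (greedy sequence-identity clustering and
    Taylor-Butina fingerprint clustering), deterministic baseline featurizers
    standing in for frozen language-model embeddings, a zoo of predictor heads
    (elastic net, linear SVM/SVR, gradient-boosted trees, MLP, CNN,
    transformer), a cross-attention multitask binding-affinity regressor on a
    unified -log10 molar scale, transfer-learned half-life regression,
    log-uniform hyperparameter search, and seeded synthetic-data generators
    that emulate the statistical structure of each task.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    glmnet,
    jsonlite,
    data.table,
    Biostrings,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
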