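Package: hetdti
Title: Drug-Target Interaction Prediction from Heterogeneous Biological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-target interactions (DTIs) by densifying a sparse
    drug-target network with attention-fused meta-path counts, fusing
    multi-view drug and target similarities with information-entropy weights,
    learning node embeddings with a graph convolutional autoencoder
    regularized by spatial topological consistency and by global, local and
    prior mutual-information objectives, and classifying drug-target pairs
    from embedding-derived features with gradient boosting. Includes a
    synthetic heterogeneous-network generator with planted group structure,
    leakage-aware five-fold cross-validation, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    pROC,
    randomForest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
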