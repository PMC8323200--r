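Package: icdcaps
Title: Capsule Networks with Joint Label Embeddings for Automated ICD-9 Coding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-label assignment of 3-digit ICD-9 diagnosis categories to
    free-text clinical notes with a hybrid neural coder: a bidirectional LSTM
    encoder, a joint label-embedding framework that injects code-description
    knowledge before and after encoding, and a capsule network whose dynamic
    routing both classifies and attributes predictions to n-gram windows.
    Includes corpus preprocessing (ICD-9 rollup, label-space selection,
    splitting), word2vec embedding I/O, the full training engine (Adam,
    early stopping) implemented in C++, the evaluation suite (micro/macro F1,
    top-10 recall, frequency-binned macro AUC, error breakdown),
    routing-strength interpretability, a synthetic clinical-corpus generator
    with planted label-keyword structure, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
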