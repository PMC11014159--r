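Package: audiograph
Title: Graph-Based Audio Classification with Graph Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Treats a collection of audio recordings as a graph: deep audio
    embeddings (VGGish-, YAMNet- or PANNs-style feature vectors) become node
    features, a k-nearest-neighbour graph in embedding space supplies the
    edges, and transductive node classification is solved with from-scratch
    implementations of three message-passing architectures (GCN, GraphSAGE,
    GAT) including hand-derived backward passes and an Adam optimiser.
    Provides delimited-text I/O for embedding tables and edge lists, a
    synthetic embedding generator with controllable class separation,
    predefined-fold cross-validation and stratified holdout evaluation,
    random-search hyperparameter optimisation over the neighbour count and
    hidden width, exact trainable-parameter counting, and a command-line
    pipeline driver.
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
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
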