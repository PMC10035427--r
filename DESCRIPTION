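Package: bfnGCN
Title: Node Features and Spectral Graph Convolutional Networks for Brain
    Functional Network Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the choice of node features affects
    graph-convolutional-network classification of brain functional networks.
    Estimates per-subject connectivity from ROI time series by Pearson
    correlation, sparse representation (regional lasso) or low-rank
    representation (singular-value soft-thresholding); builds node feature
    matrices from original signals, one-hot indicators, graph node statistics
    or correlation vectors; trains a two-layer spectral GCN with a mean/max
    readout; and evaluates classifiers with repeated random-split protocols
    reporting accuracy, sensitivity, specificity, precision, F1 and AUC.
    Includes a synthetic cohort generator with controllable group-level
    covariance structure so the full pipeline is testable without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
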