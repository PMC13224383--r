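Package: spagranger
Title: Spatial Granger Causality on Potential-Oriented Cell Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers directional regulator-to-target gene relationships
    (transcription factor to target, ligand to receptor) from spatial
    transcriptomics. A smooth scalar spatial potential ("isodepth") is
    learned from expression and coordinates, a k-nearest-neighbor graph of
    cells is oriented along decreasing potential into a directed acyclic
    graph, and a sparse-input neural autoregressive model with
    hierarchical group-lasso regularization over graph lags is trained by
    proximal gradient descent to score candidate gene pairs. Includes a
    synthetic-data generator with planted lagged interactions, a classical
    vector-autoregression oracle for the path-graph limit, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
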