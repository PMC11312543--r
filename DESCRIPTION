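Package: parafac2sc
Title: PARAFAC2 Tensor Decomposition for Multi-Condition Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits the PARAFAC2 (Pf2) decomposition to ragged collections of
    cell-by-gene expression matrices, one per experimental condition, where the
    number of cells differs across conditions. Conditions are coupled through
    per-condition orthonormal cell projections onto a shared low-rank frame,
    separating condition-level variation (condition factors), latent cell
    eigen-states, and gene signatures. Includes the accompanying normalization
    pipeline (gene filtering, counts-per-million scaling, delta-method log
    transform, centering), post-factorization alignment conventions (unit-scale
    components, sign fixing, Gini ordering), factor-match-score stability
    protocols (cell subsampling and bootstrapping), cell-type ablation
    experiments, a synthetic-data generator with planted factors, and a
    leave-one-batch-out L1-logistic association workflow on condition factors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    glmnet,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
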