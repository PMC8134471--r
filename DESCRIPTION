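Package: cpmkit
Title: Connectome-Based Predictive Modeling of Behavior from Functional
    Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Connectome-based predictive modeling (CPM) of dimensional
    behavior scores from task functional connectivity matrices.  Builds
    Fisher z-transformed connectomes from node time series, selects
    behavior-correlated edges within cross-validation folds (with optional
    partial-correlation covariate adjustment), fits positive/negative
    network-strength models, evaluates repeated k-fold cross-validation by
    Spearman correlation and RMSE, derives significance by permutation of
    the behavior-connectome correspondence, compares dependent model
    correlations with Steiger's z, and localizes consensus networks at the
    node, hemisphere, distance, and canonical-network level.  Includes a
    synthetic connectome generator with planted, condition-specific
    brain-behavior signal so the full pipeline is testable without
    clinical imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
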