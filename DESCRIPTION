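Package: connectopred
Title: Predicting Cortical Connectome Projections from Cytoarchitecture and Border Distance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Tools for analysing and predicting inter-areal corticocortical
    connectivity from structural variables. Computes border distances on a
    parcellation adjacency graph, cytoarchitectonic structural-type and
    hierarchical-level differences for ordered area pairs, ordinal
    association statistics (Spearman, Wilcoxon rank-sum, Kruskal-Wallis,
    Jonckheere-Terpstra), a co-occurrence-normalised two-class linear
    discriminant model that predicts the existence of unexamined
    projections at configurable posterior thresholds with holdout
    cross-validation, and node-level topology summaries (degree, weighted
    degree, connection range, module and hub comparisons, undersampling
    robustness). A seeded synthetic-connectome generator emulates the
    assumed statistical structure so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
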