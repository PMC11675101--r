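Package: tractgraph
Title: Graph-Theoretic Analysis of Probabilistic Tractography Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for structural-connectome analysis of probabilistic
    tractography streamline matrices. Reads per-subject directed ROI-by-ROI
    streamline counts, normalizes them by per-seed waytotals, symmetrizes and
    aggregates them into group graphs, sweeps proportional weight thresholds,
    and admits thresholded graphs by connectedness, maximized Newman
    modularity, and small-worldness against degree-preserving null networks.
    Provides shortest-path distance ranking of parieto-premotor connections,
    a two-stage hub taxonomy built on the participation coefficient,
    within-module degree z-score, strength, and betweenness centrality, and
    edge-wise paired lateralization tests with false-discovery-rate control.
    Includes a synthetic-cohort generator with planted modules, hubs, and
    hemispheric asymmetries for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
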