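Package: neoconn
Title: Neonatal Structural Connectome Analysis with Network-Based Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Graph-theoretical analysis of neonatal structural brain connectomes
    and their association with toddler behavioural outcomes. Provides a data
    model and delimited-text I/O for weighted undirected connectomes, cohort
    covariate tables and parcellation node tables; cost-corrected graph metrics
    (strength, degree, global/local/nodal efficiency) over a proportional
    thresholding density sweep; core-periphery decomposition by a Kernighan-Lin
    style label search with core/feeder/peripheral edge typing; network-based
    statistics (edgewise general linear models, supra-threshold component
    extent, Freedman-Lane permutation family-wise error control, and a
    t-threshold sensitivity sweep); covariate-adjusted partial Spearman
    correlations with Benjamini-Hochberg false discovery rate control; and a
    synthetic cohort simulator with planted core-periphery structure and
    planted edge-weight-behaviour effects so every stage is testable without
    access to clinical data. A config-driven pipeline orchestrates the stages
    end to end with deterministic seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
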