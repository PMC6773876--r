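Package: apear
Title: Active-Subnetwork-Oriented Pathway Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies active subnetworks - connected subgraphs of a
    protein-protein interaction network that are predominantly composed of
    significantly altered genes - and performs over-representation analysis
    on them. Subnetworks are scored by aggregating gene-level z scores and
    calibrated against a Monte Carlo background; search is available via a
    greedy seed-expansion algorithm, simulated annealing, or a genetic
    algorithm. Enriched gene sets are aggregated over multiple search
    iterations, clustered by pairwise kappa statistics (hierarchical with
    silhouette-based selection of the number of clusters, or fuzzy
    multi-membership), and pathway activity can be scored per sample from an
    expression matrix. Includes seedable synthetic-data generators (networks
    with planted modules, differential-expression tables, gene set
    collections, expression matrices) so the whole pipeline can be exercised
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    jsonlite
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
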