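Package: bionetcomm
Title: Topological and Functional Comparison of Community Detection in
    Biological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community detection and comparison toolkit for biological
    interaction networks. Implements six modularity-family detection
    algorithms (Girvan-Newman, fast greedy agglomeration, Louvain,
    leading-eigenvector bisection, Potts spin-glass annealing, Combo, and
    the kappa-path-centrality CONCLUDE variant) together with partition
    quality and similarity metrics (modularity, Rand, adjusted Rand,
    normalized mutual information, Jaccard matrices with community
    matching), hypergeometric pathway enrichment with fold-enrichment
    comparison of matched communities, a node-deletion robustness
    analysis, and seeded generators for planted-partition networks with
    pathway annotations and ortholog tables so the full pipeline runs
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    fgsea,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
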