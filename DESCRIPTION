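Package: amyloidnet
Title: Assembly and Topological Analysis of the Amyloid Protein-Protein Interaction Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Assembles a protein-protein interaction network around a curated
    set of amyloidogenic seed proteins from PSI-MITAB 2.5 interaction records,
    applying taxon, molecule-type, self-loop and duplicate curation filters.
    Characterizes the assembled network (density, clustering coefficient,
    characteristic path length, degree and betweenness distributions,
    power-law fits, Erdos-Renyi null-model comparison, hub and bottleneck
    calling), simulates robustness under random failure and centrality-ordered
    attack, partitions the network with a native Markov Clustering (MCL)
    implementation, and performs hypergeometric over-representation analysis
    with Benjamini-Hochberg correction on generic annotation tables. A
    synthetic-data module generates scale-free and planted-partition networks,
    annotation tables with planted enriched terms, and MITAB files with known
    contamination so every stage is testable offline with exact ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
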