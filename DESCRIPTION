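Package: treecloud
Title: Congruence of Bayesian Gene-Tree Posteriors in Treespace
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies, tests and visualizes the agreement between Bayesian
    posterior distributions of gene trees ("treeclouds") and a reference
    treecloud such as one estimated from concatenated universal proteins.
    Provides symmetric (Robinson-Foulds topology) and branch-length
    tree-to-tree distances, exact maximum agreement subtree (MAST)
    computation and the derived SPR-surrogate distance, Ge's gamma
    statistic for screening horizontal gene transfer, subsampled
    within- and between-cloud distance estimation, non-metric
    multidimensional scaling of treecloud space, a rank-based test of the
    centrality of the reference treecloud, the treeishness statistic tau,
    Welch-t/percentile-overlap incongruence screens, and a simulator of
    posterior-like treeclouds with controlled congruence structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    phytools,
    vegan,
    Rcpp,
    jsonlite,
    withr,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
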