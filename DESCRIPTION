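Package: rankdelta
Title: Rank-Based Comparison of Weighted Connectivity Network Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares two groups of weighted networks (e.g. functional brain
    connectivity matrices from two experimental conditions) through the
    statistics of their link-weight rankings. Link weights are ranked within
    each network, per-rank medians and standard deviations are computed within
    each group, and their between-group log2 ratios (Delta-M, Delta-Std) are
    visualised in a scatter plane with subsampling uncertainty boxes. Includes
    seeded synthetic benchmark generators, functional-network reconstruction
    from multichannel time series (absolute Pearson correlation, Granger
    causality, k-nearest-neighbour mutual information and transfer entropy),
    extensions to topological link and node metrics, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    igraph,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
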