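Package: netaggr
Title: Ensemble Aggregation of Gene Networks by Inverse Rank Products
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Merges weighted undirected gene networks into a single consensus
    network with a non-parametric inverse-rank-product scheme. Networks may
    come from bootstrap subsamples of one expression dataset, from different
    reconstruction algorithms (sparse symmetric partial correlation,
    shrinkage partial correlation, soft-thresholded correlation), or from
    different datasets measuring the same genes. Includes a scale-free
    network simulator with conditional-normal expression data, ROC/AUC and
    precision-recall evaluation against a gold standard, and permutation
    significance for aggregated edges.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
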