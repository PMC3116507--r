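Package: hgtscan
Title: Genome-Wide Detection of Horizontal Gene Transfer by Phylogenetic Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for detecting horizontally transferred genes in an
    insect proteome by taxon-profile homology screening, an explicit filter
    cascade with a stage-count ledger, phylogenetic validation (JTT+Gamma+I
    likelihood, neighbor-joining on maximum-likelihood distances, bootstrap
    support, Shimodaira-Hasegawa topology tests against a constrained
    vertical-inheritance tree), and downstream functional analysis
    (coexpression pathway scoring, hypergeometric enrichment, SNP-list
    overlap). Includes a synthetic-data generator that simulates taxon-
    labeled proteomes with implanted transfer events so the whole cascade
    is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    igraph,
    jsonlite,
    stats,
    utils,
    generics,
    limma,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Matrix,
    rtracklayer,
    GenomicRanges,
    IRanges,
    withr
Config/testthat/edition: 3
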