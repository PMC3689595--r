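Package: genoverlap
Title: Detection and Comparative Evolutionary Analysis of Positionally
    Overlapping Genes
Version: 0.1.0
Authors@R:
    person("genoverlap", "developers", email = "genoverlap@example.org",
           role = c("aut", "cre"))
Description: Detects positionally overlapping gene pairs from genome
    annotations and classifies them as nested (embedded/host) or partially
    overlapping, with relative orientation and overlapping-cluster handling.
    Combines per-species overlap calls with one-to-one ortholog maps to
    quantify retention and rearrangement of overlapping pairs across
    genomes, including young/old pair age classes, cross-species
    localization profiles, intron-count and intronless contingency tables,
    and expression correlation by orientation.  Ships a microsatellite
    (SSR) scanner for perfect and imperfect 1-6 bp motifs with fixed
    mismatch penalty and consecutive-mismatch exclusion, a statistics kit
    (Yates-corrected chi-square, Spearman rank correlation with exact
    small-sample permutation, Mantel and multi-matrix Mantel permutation
    tests, binary logit regression by iteratively reweighted least squares,
    likelihood-ratio tests, average-linkage city-block clustering), and
    maximum-likelihood dependent/independent models of correlated binary
    trait evolution on phylogenies with simulation support.  Synthetic-data
    generators with known ground truth and a command-line pipeline make
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    methods,
    Rcpp,
    rtracklayer,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
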