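Package: dtubench
Title: Benchmarking Differential Transcript Usage Detection with
    Counting-Bin Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates bulk RNA-seq experiments with known differential
    transcript usage (DTU), builds alternative counting-bin
    representations of a transcript catalog (disjoint flattened exon
    bins with or without aggregation of overlapping genes, original
    exons, junction-spanning fragments, transcript-level bins quantified
    by an equivalence-class EM), tests each bin for differential usage
    with a bin-versus-rest negative binomial generalized linear model
    with Cox-Reid dispersion estimation and empirical-Bayes shrinkage,
    aggregates bin-level p-values to gene-level q-values, and evaluates
    the true positive rate and false discovery rate stratified by gene
    characteristics such as isoform number and isoform dominance.
    Includes isoform prefiltering and annotation-degradation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
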