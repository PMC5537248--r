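Package: tilscape
Title: Multi-Region Tumor Immune Repertoire, Mutation Phylogeny and
    Immune Signature Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrative analysis of spatially separated tumor samples
    profiled by T cell receptor (TCR) repertoire sequencing, exome
    sequencing and expression microarrays.  Provides TCR-beta clonotype
    repertoire statistics (Shannon-Wiener diversity, clone frequency
    spectra, cumulative TOP-N curves, pairwise repertoire overlap
    matrices, shared-clone extraction and rank-based group tests),
    a somatic variant filtering cascade with germline-rooted maximum
    parsimony phylogeny reconstruction over binary mutation profiles,
    single-sample pathway activity scoring by a rank-based random walk
    over kernel-smoothed expression statistics with a Spearman screen
    against repertoire diversity, coefficient-of-variation based
    extraction of stably expressed signature genes with two-cluster
    survival stratification (Kaplan-Meier, log-rank), and seeded
    synthetic-data generators that emulate each input so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    limma,
    Rcpp,
    stats,
    survival,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
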