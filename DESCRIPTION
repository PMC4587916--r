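Package: grnbench
Title: Reproducible Benchmarking of Gene Regulatory Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible benchmarking framework for gene regulatory
    network (GRN) inference from steady-state expression data. Generates
    synthetic datasources (power-law directed acyclic topologies with
    knockout or multifactorial steady-state expression), subsamples them
    into homogeneous datasets contaminated with controlled local (per-gene
    Gaussian) and global (dataset-wide lognormal) noise, runs a battery of
    natively implemented inference algorithms (CLR, ARACNE, MRNET, MRNETB,
    C3NET, MutRank, Zscore, PCIT, relevance networks, shrinkage partial
    correlation, and a random-forest importance method), and scores them
    against the gold-standard network with a top-edges precision/recall
    protocol (AUPR, AUROC, mean precision on the best fraction of possible
    edges). Includes replicate benchmarking with Wilcoxon rank-sum winner
    flagging, rank aggregation across datasources, and noise- and
    sample-size-sensitivity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    ranger,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
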