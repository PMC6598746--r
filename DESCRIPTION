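Package: phyloconflict
Title: Stepwise Multi-Locus Phylogenetic Incongruence Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects reticulate evolution (putative hybrids) in multi-locus
    sequence data by a stepwise incongruence workflow: incongruence length
    difference (partition homogeneity) permutation tests on gap-as-fifth-state
    maximum parsimony, reciprocal Approximately Unbiased and
    Shimodaira-Hasegawa topology tests driven by RELL multiscale
    bootstrapping, agreement-based identification of irreconcilable taxa
    between gene trees, rule-based raw-sequence verification of flagged
    samples, and amplicon background-population profiling to weigh
    hybridisation against incomplete lineage sorting. Includes a synthetic
    multi-locus data generator with planted hybrids, divergent-sequence and
    autapomorphy confounders, and incomplete-lineage-sorting scenarios with
    full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
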