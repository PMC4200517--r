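Package: phylomarkr
Title: Marker Selection, Congruence Scoring and Topology Diagnostics for
    Phylogenomic Supermatrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for building and stress-testing
    phylogenomic marker sets from multi-gene amino-acid data. Implements
    ortholog-group filtering by taxon coverage and relative coding length,
    hidden-paralog vetting and per-taxon gene-tree/species-tree congruence
    scoring on support-condensed trees, gene ranking and ranked accumulation,
    random gene-subsampling experiments with clade-recovery curves,
    long-branch (LB) score and substitution-saturation (p-distance versus
    patristic distance regression) diagnostics, parsimony-informative-site
    partitioning of gene sets, exhaustive backbone-topology enumeration with
    Fitch/Sankoff parsimony step counting on multistate morphological
    matrices, and Mk-model marginal ancestral-state reconstruction with
    lineage-novelty detection. A seeded synthetic-data generator (Yule
    species trees, NNI or multispecies-coalescent gene-tree discordance,
    gamma-rate amino-acid alignments, injected long-branch taxa and
    saturated genes, Mk-evolved characters with event logs) provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    phangorn,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    seqinr,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr
Config/testthat/edition: 3
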