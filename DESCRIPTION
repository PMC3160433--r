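Package: forestnet
Title: Forest- and Network-Based Analysis of Lateral Gene Transfer in
    Bacterial Pangenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Alternatives to single-tree ("tree of life") analysis for
    studying genomic fluidity in bacteria such as Escherichia coli.
    Clusters all-vs-all homology hits into gene families by single
    linkage (true or false bidirectional-best-hit modes), builds
    identity-sliced genome networks and sequence-level gene networks
    with topological classification of connected components, performs
    clanistic harvesting of phylogenetic forests (clans, slices,
    melange, the E* equitability index, the p-score, candidate mobile
    pathogenicity modules), and implements the polychromatic-quartet
    (PQ) method: quartet sampling from gene trees, strain-pair clan
    frequency matrices, one-complement distance matrices exported as
    Nexus for split-network software, and a Mantel permutation test for
    group-structured transfer. A synthetic-forest generator with a
    known ground truth supports desk-scale validation of every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    phytools,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    phangorn,
    rmarkdown,
    testthat (>= 3.0.0),
    vegan,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
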