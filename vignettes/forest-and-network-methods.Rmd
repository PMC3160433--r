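---
title: "Forests and networks instead of a tree of life"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forests and networks instead of a tree of life}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestnet)
library(dplyr)
```

## Why not one tree?

In bacteria, lateral gene transfer (LGT) moves genes between lineages —
often carried by plasmids and viruses (mobile genetic elements, MGEs) — so
different genes tell different evolutionary stories. Forcing a pangenome
into a single species tree averages those stories away. `forestnet`
implements the alternative: analyse the whole *forest* of gene trees and
the *networks* of sequence sharing, and quantify how much transfer
structures them.

The package covers five method families:

1. **Gene families** from all-vs-all homology hits (single linkage,
   optionally restricted to reciprocal best hits).
2. **Genome networks**: genomes connected by shared families inside an
   identity band — the `[100, 100]` band isolates candidate *recent*
   transfers.
3. **Gene networks**: sequences connected by homology; component topology
   (density, articulation points, communities) separates conserved
   families from tinkered ones.
4. **Clanistics**: for each gene tree, can a category of leaves (the
   "natives") be isolated by one edge cut (perfect clan), two cuts
   (perfect slice), or not at all (melange)? Scored with the E*
   equitability index and the parsimony p-score.
5. **Polychromatic quartets (PQ)**: quartets of leaves from four distinct
   strains vote on which strain pairs travel together; the pooled
   frequencies give a transfer-aware distance between strains, testable
   for group structure with a Mantel permutation test and exportable to
   split-network software.

All tree inputs are unrooted `ape::phylo` objects; graphs are `igraph`
objects; every tabular argument and result is a tibble.

## A synthetic pangenome

Real analyses start from Newick forests (`read_forest()`), tabular
homology hits (`read_hits()`) and a leaf annotation table
(`read_annotations()`). For a self-contained tour we simulate a pangenome
with known ground truth: a species tree, gene trees perturbed by LGT
(biased towards same-pathogenicity donor-recipient pairs), MGE leaves
hitchhiking on transfers, and bootstrap supports that are high on
species-tree-concordant edges and mixed on transfer edges.

```{r simulate}
sim <- simulate_forest(
  n_strains = 12, n_trees = 120, core_fraction = 0.4,
  lgt_rate = 2, within_group_bias = 3, seed = 42)
sim$forest
head(sim$annotations, 3)
```

## Clanistic harvesting

A *clan* is one side of a bipartition: the leaf set obtained by a single
edge cut of an unrooted tree. A *slice* is the middle component left by
two cuts. For each tree we ask whether the native category — here, the
strains, against outgroups and MGEs — forms a perfect clan, a perfect
slice, or a melange, and we quantify mixing with two indices:

* **p-score**: the parsimony score of the native/intruder character — the
  minimum number of edge cuts separating natives from intruders (0 = pure,
  1 = perfect clan, 2 = perfect slice). Computed with Hartigan's
  algorithm, which is exact on the polytomies produced by collapsing
  poorly supported edges.
* **E\***: Shannon equitability of the sizes of the maximal native-pure
  clans; 0 when natives stay together, 1 when maximally interleaved.

```{r clanistics}
report <- classify_forest(sim$forest, sim$annotations,
                          values = paste0("EC", 1:12),
                          support_cutoff = 50)
forest_summary(report)$counts
forest_summary(report)$mean_e_star_melange
```

Weakly supported edges (`< 50%` bootstrap) are collapsed before
classification, so poorly resolved conflict does not masquerade as
transfer. Groups of MGE-carrying, pathogen-only trees with identical
strain content — candidate mobile pathogenicity modules — are reported by
`find_mobile_modules()`.

## Polychromatic quartets

The PQ protocol repeats, per tree: draw four distinct strains (one leaf
copy each), restrict the tree to those leaves, and accept the induced
bipartition if at least one edge on the separating path has bootstrap
support at or above the cutoff (edges without a value count as
supported). An accepted quartet credits its two same-clan strain pairs
and counts all six pairs as co-sampled; counts are pooled over the forest
by summation and the frequency of a pair is its same-clan count over its
co-occurrence count.

```{r pq}
pqm <- pq_forest(sim$forest, sim$annotations, n_quartets = 500, seed = 42)
pqm
tidy(pqm) |> arrange(desc(frequency)) |> head(3)
```

The one-complement of the frequency matrix is a distance: 0 for pairs
that always share a clan, 1 for pairs that never do. It can be written as
a Nexus `DISTANCES` block for Neighbor-Net (`write_nexus_distances()`),
and tested for pathogenicity structure with a one-tailed Mantel
permutation test (are between-group distances larger than within-group?):

```{r mantel}
d <- pq_distance(pqm)
strain_groups <- sim$annotations |>
  filter(grepl("^EC", taxon_class)) |>
  distinct(taxon_class, pathogenicity) |>
  (\(x) setNames(x$pathogenicity, x$taxon_class))()
mantel_test(d, strain_groups, n_permutations = 999, seed = 42)
```

Because this forest was simulated with a 3-fold same-group transfer bias,
the test should usually (not always — it is a stochastic simulation)
reject the null. `partition_forest()` splits the forest into core trees
(all strains), shell trees, and single-copy trees so the analysis can be
repeated per compartment, and `compare_distance_sets()` contrasts core
and shell mean distances.

## Families and networks

The same machinery runs on homology hits. `simulate_hits()` plants gene
families with a "recent transfer" band at 100% identity linking a cell
and a mobile element:

```{r networks}
hs <- simulate_hits(n_families = 20, n_spurious = 5, seed = 42)
fam <- cluster_families(hs$hits, annotations = hs$annotations)
gnet <- build_genome_network(fam, hs$hits, hs$annotations,
                             identity_band = c(100, 100))
find_recent_transfer_candidates(gnet) |> head(3)
```

A family joins a genome-pair edge when the *maximum* cross-genome
member-pair identity falls in the band; edge display weights are inverse
shared-family counts. `summarize_categories()` tabulates the shared
sequences and families per functional category with percentages of the
computed column totals.

The sequence-level gene network classifies each connected component by
topology — `clique_like` (dense, no cut vertices: conserved families),
`bridged` (sparse or held together by high-betweenness articulation
points: fusion/transfer signatures) or `intermediate`:

```{r gene-net}
snet <- build_gene_network(hs$hits, hs$annotations)
classify_topology(component_metrics(snet)) |>
  count(topology_class)
```

## Reproducibility

Every stochastic entry point takes a `seed`; the command-line interface
(`system.file("cli", "forestnet.R", package = "forestnet")`) writes a
`run_manifest.json` with parameters, input digests and the package
version, so any run can be replayed exactly.
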