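# Polychromatic quartets (PQ): dissect every gene tree into sampled
# four-strain quartets, tally which strain pairs fall in the same clan of
# the supported quartet bipartition, pool the tallies over the forest into
# a strain-pair frequency matrix, and take its one-complement as a
# transfer-sensitive distance between strains.

# Precompute, for one tree, the clan bipartitions of its internal edges as
# a logical matrix (edge x tip: TRUE on the child side) plus a per-edge
# support flag (edges without a support value count as supported).
pq_prepare <- function(tree, support_cutoff = 50) {
  n_tip <- ape::Ntip(tree)
  if (n_tip >= 4 && ape::is.rooted(tree)) {
    # Rooted input: the two root-child edges duplicate one bipartition and
    # support conventions label only one of them; share the label so the
    # unlabelled twin cannot sneak the split past the cutoff.
    tree <- mirror_root_support(tree)
  }
  sup <- node_supports(tree)
  internal_edge <- tree$edge[, 2] > n_tip
  child <- tree$edge[internal_edge, 2]
  if (length(child) == 0) {
    return(list(masks = matrix(FALSE, 0, n_tip), support_ok = logical(0),
                tips = tree$tip.label))
  }
  parent <- parent_vector(tree)
  below <- matrix(FALSE, nrow = n_tip + tree$Nnode, ncol = n_tip)
  below[cbind(seq_len(n_tip), seq_len(n_tip))] <- TRUE
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(ord))) {
    below[ord[i, 1], ] <- below[ord[i, 1], ] | below[ord[i, 2], ]
  }
  edge_sup <- sup[child - n_tip]
  list(masks = below[child, , drop = FALSE],
       support_ok = is.na(edge_sup) | edge_sup >= support_cutoff,
       tips = tree$tip.label)
}

# Resolve the quartet given tip indices i (length 4) against prepared masks.
# Returns 0 (unresolved) or 1/2/3 for splits 12|34, 13|24, 14|23; sign
# negative when resolved topologically but failing the support rule.
resolve_quartet <- function(prep, i) {
  m <- prep$masks[, i, drop = FALSE]
  if (nrow(m) == 0) return(0L)
  pairings <- list(c(1L, 2L, 3L, 4L), c(1L, 3L, 2L, 4L), c(1L, 4L, 2L, 3L))
  for (k in 1:3) {
    p <- pairings[[k]]
    sep <- (m[, p[1]] & m[, p[2]] & !m[, p[3]] & !m[, p[4]]) |
      (!m[, p[1]] & !m[, p[2]] & m[, p[3]] & m[, p[4]])
    if (any(sep)) {
      return(if (any(prep$support_ok[sep])) k else -k)
    }
  }
  0L
}

.split_pairs <- list(
  rbind(c(1L, 2L), c(3L, 4L)),
  rbind(c(1L, 3L), c(2L, 4L)),
  rbind(c(1L, 4L), c(2L, 3L))
)

#' Induced quartet topology of four leaves
#'
#' Restricts the tree to four leaves and reports the induced bipartition,
#' provided at least one edge on the internal path separating the two pairs
#' has support at or above `support_cutoff` (edges without a support value
#' count as supported). A star restriction, or a resolved restriction whose
#' separating path is entirely unsupported, is `unresolved`.
#'
#' @param tree A `phylo`.
#' @param leaves Four distinct leaf labels present in the tree.
#' @param support_cutoff Bootstrap percent for accepting the bipartition
#'   (default 50).
#' @return A list: `resolved` (logical) and `clans` (list of the two leaf
#'   pairs when resolved, otherwise `NULL`).
#' @export
induced_quartet_topology <- function(tree, leaves, support_cutoff = 50) {
  if (length(leaves) != 4 || anyDuplicated(leaves) > 0) {
    stopf("leaves must be 4 distinct labels")
  }
  idx <- match(leaves, tree$tip.label)
  if (anyNA(idx)) {
    stopf("leaf/leaves not in tree: %s",
          paste(leaves[is.na(idx)], collapse = ", "))
  }
  prep <- pq_prepare(tree, support_cutoff)
  k <- resolve_quartet(prep, idx)
  if (k <= 0) return(list(resolved = FALSE, clans = NULL))
  sp <- .split_pairs[[k]]
  list(resolved = TRUE,
       clans = list(leaves[sp[1, ]], leaves[sp[2, ]]))
}

#' Sample polychromatic quartets from one gene tree
#'
#' Repeats `n_quartets` times: draw four distinct strains uniformly from
#' the strains present in the tree, draw one leaf copy per strain uniformly
#' when a strain has several copies, resolve the induced quartet topology
#' ([induced_quartet_topology()]), and on success credit the two same-clan
#' strain pairs and count all six strain pairs of the quartet as
#' co-sampled. Unresolved quartets contribute nothing. Sampling is with
#' replacement across draws.
#'
#' @param tree A `phylo`.
#' @param strain_map Named character vector, leaf label -> strain id, for
#'   the leaves that belong to a strain (others are ignored).
#' @param n_quartets Number of sampled quartets (default 1000).
#' @param support_cutoff Bootstrap inclusion rule (default 50).
#' @param strains Strain universe for the tally matrices (default: strains
#'   seen in `strain_map`).
#' @param exhaustive Enumerate every four-strain subset exactly once
#'   instead of sampling (`n_quartets` is then ignored; one leaf copy per
#'   multi-copy strain is still drawn uniformly per quartet).
#' @return A list of two integer matrices, `cooccurrence` and `same_clan`
#'   (strain x strain, symmetric), or `NULL` (with a message) when the tree
#'   holds fewer than four distinct strains.
#' @export
sample_pqs <- function(tree, strain_map, n_quartets = 1000,
                       support_cutoff = 50, strains = NULL,
                       exhaustive = FALSE) {
  leaf_strain <- strain_map[names(strain_map) %in% tree$tip.label]
  strains <- strains %||% sort(unique(unname(strain_map)))
  present <- sort(unique(unname(leaf_strain)))
  if (length(present) < 4) {
    inform(sprintf("tree skipped: %d strain(s) < 4", length(present)))
    return(NULL)
  }
  prep <- pq_prepare(tree, support_cutoff)
  tip_index <- setNames(match(names(leaf_strain), tree$tip.label),
                        names(leaf_strain))
  copies <- split(unname(tip_index), unname(leaf_strain))
  n_s <- length(strains)
  cooc <- matrix(0L, n_s, n_s, dimnames = list(strains, strains))
  same <- matrix(0L, n_s, n_s, dimnames = list(strains, strains))
  present_idx <- match(present, strains)
  if (exhaustive) {
    picks <- utils::combn(length(present), 4)
  }
  n_draws <- if (exhaustive) ncol(picks) else n_quartets
  for (q in seq_len(n_draws)) {
    pick <- if (exhaustive) picks[, q] else sample.int(length(present), 4)
    tips <- vapply(copies[present[pick]], function(tt) {
      if (length(tt) == 1L) tt else tt[sample.int(length(tt), 1)]
    }, integer(1))
    k <- resolve_quartet(prep, tips)
    if (k <= 0) next
    si <- present_idx[pick]
    for (a in 1:3) for (b in (a + 1):4) {
      cooc[si[a], si[b]] <- cooc[si[a], si[b]] + 1L
      cooc[si[b], si[a]] <- cooc[si[b], si[a]] + 1L
    }
    sp <- .split_pairs[[k]]
    for (row in 1:2) {
      i <- si[sp[row, 1]]; j <- si[sp[row, 2]]
      same[i, j] <- same[i, j] + 1L
      same[j, i] <- same[j, i] + 1L
    }
  }
  list(cooccurrence = cooc, same_clan = same)
}

#' Run the PQ protocol over a forest and assemble the strain-pair matrix
#'
#' Samples polychromatic quartets from every eligible tree (at least four
#' distinct strains) and pools the tallies by summation, so trees weigh in
#' proportion to the information they contribute. Frequencies are
#' recomputed from the pooled counts: per pair, the number of quartets in
#' which the pair sat in the same clan over the number of quartets in which
#' the pair was co-sampled. Pairs never co-sampled are flagged missing.
#'
#' @param forest A `gene_forest` (or list of `phylo`).
#' @param annotations Annotation table; leaves whose `taxon_class` is a
#'   strain id (`EC*`) are mapped to that strain.
#' @param strains Strain universe (default: all strain classes seen).
#' @param n_quartets Quartets sampled per tree (default 1000).
#' @param support_cutoff Bootstrap inclusion rule (default 50).
#' @param seed Optional RNG seed for reproducible sampling.
#' @param tree_ids Optional subset of trees to analyse (e.g. the core set
#'   from [partition_forest()]).
#' @param exhaustive Enumerate all four-strain subsets per tree instead of
#'   sampling (see [sample_pqs()]).
#' @return A `pq_matrix`: list with `strains`, `cooccurrence`, `same_clan`,
#'   `frequency` (NA where never co-sampled) and `n_trees_sampled`.
#' @export
pq_forest <- function(forest, annotations, strains = NULL, n_quartets = 1000,
                      support_cutoff = 50, seed = NULL, tree_ids = NULL,
                      exhaustive = FALSE) {
  forest <- as_gene_forest(forest)
  if (!is.null(tree_ids)) forest <- as_gene_forest(forest[tree_ids])
  if (!is.null(seed)) set.seed(seed)
  strain_map <- strain_map_from_annotations(annotations)
  strains <- strains %||% sort(unique(unname(strain_map)))
  n_s <- length(strains)
  cooc <- matrix(0L, n_s, n_s, dimnames = list(strains, strains))
  same <- matrix(0L, n_s, n_s, dimnames = list(strains, strains))
  n_used <- 0L
  for (tree in forest) {
    res <- withCallingHandlers(
      sample_pqs(tree, strain_map, n_quartets = n_quartets,
                 support_cutoff = support_cutoff, strains = strains,
                 exhaustive = exhaustive),
      message = function(m) invokeRestart("muffleMessage"))
    if (is.null(res)) next
    cooc <- cooc + res$cooccurrence
    same <- same + res$same_clan
    n_used <- n_used + 1L
  }
  freq <- ifelse(cooc > 0, same / pmax(cooc, 1L), NA_real_)
  diag(freq) <- NA_real_
  structure(list(strains = strains, cooccurrence = cooc, same_clan = same,
                 frequency = freq, n_trees_sampled = n_used,
                 n_quartets = n_quartets, support_cutoff = support_cutoff),
            class = "pq_matrix")
}

# Leaf -> strain map: annotation rows whose taxon_class is a strain (EC*).
strain_map_from_annotations <- function(annotations) {
  is_strain <- grepl("^EC\\d+$", annotations$taxon_class)
  setNames(annotations$taxon_class[is_strain],
           annotations$sequence_id[is_strain])
}

#' @export
print.pq_matrix <- function(x, ...) {
  obs <- sum(!is.na(x$frequency[upper.tri(x$frequency)]))
  cat(sprintf("<pq_matrix> %d strains (%d pair slots, %d observed), %d tree(s) sampled\n",
              length(x$strains), choose(length(x$strains), 2), obs,
              x$n_trees_sampled))
  invisible(x)
}

#' One-complement PQ distance matrix
#'
#' `d(i, j) = 1 - frequency(i, j)`: strain pairs that always share a clan in
#' supported quartets are at distance 0; pairs that never do are at
#' distance 1. Pairs never co-sampled are imputed with the mean of the
#' observed off-diagonal distances (and stay flagged in the missing mask)
#' or left missing.
#'
#' @param pqm A `pq_matrix` from [pq_forest()].
#' @param impute `"mean"` (default) or `"none"`.
#' @return A [taxon_dist()].
#' @export
pq_distance <- function(pqm, impute = c("mean", "none")) {
  impute <- match.arg(impute)
  d <- 1 - pqm$frequency
  diag(d) <- 0
  miss <- is.na(d)
  diag(miss) <- FALSE
  if (all(miss[upper.tri(miss)])) stopf("no strain pair was ever co-sampled")
  if (impute == "mean" && any(miss)) {
    d[miss] <- mean(d[upper.tri(d)][!miss[upper.tri(miss)]])
  }
  taxon_dist(d, pqm$strains, missing = miss)
}

#' Partition a forest into core, shell and single-copy sets
#'
#' Core trees carry every strain; shell trees carry fewer; single-copy
#' trees carry at most one leaf per strain. PQ-eligible trees carry at
#' least four distinct strains.
#'
#' @param forest A `gene_forest`.
#' @param annotations Annotation table.
#' @param all_strains Strain universe (default: all strain classes seen in
#'   the annotations).
#' @return Tibble per tree: `tree_id`, `n_strains`, `max_copies`, and
#'   logical `core`, `shell`, `single_copy`, `pq_eligible`.
#' @export
partition_forest <- function(forest, annotations, all_strains = NULL) {
  forest <- as_gene_forest(forest)
  strain_map <- strain_map_from_annotations(annotations)
  all_strains <- all_strains %||% sort(unique(unname(strain_map)))
  purrr::imap_dfr(forest, function(tree, id) {
    st <- strain_map[names(strain_map) %in% tree$tip.label]
    tab <- table(st)
    n_strains <- length(tab)
    tibble::tibble(
      tree_id = id, n_strains = n_strains,
      max_copies = if (n_strains > 0) as.integer(max(tab)) else 0L,
      core = n_strains == length(all_strains),
      shell = n_strains > 0 && n_strains < length(all_strains),
      single_copy = n_strains > 0 && (length(tab) == 0 || max(tab) <= 1),
      pq_eligible = n_strains >= 4)
  })
}
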