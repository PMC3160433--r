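# Clanistics: classify labelled unrooted gene trees by how cleanly a
# category of interest ("natives") separates from the rest ("intruders").
# A clan is one side of a single edge cut; a slice is the middle component
# of two cuts; a melange resists both. The p-score (two-state parsimony)
# counts the minimum edge cuts separating the categories, and E* measures
# how evenly natives are scattered across the tree.

# Orient an unrooted tree from `root` (any node id): parent vector and a
# BFS order (parents before children).
orient_tree <- function(tree, root) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  adj <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1]; b <- tree$edge[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  parent <- integer(n_node)
  order <- integer(n_node)
  seen <- logical(n_node)
  queue <- integer(n_node)
  queue[1] <- root; seen[root] <- TRUE
  head_i <- 1L; tail_i <- 1L
  while (head_i <= tail_i) {
    v <- queue[head_i]
    order[head_i] <- v
    head_i <- head_i + 1L
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        parent[w] <- v
        tail_i <- tail_i + 1L
        queue[tail_i] <- w
      }
    }
  }
  list(parent = parent, order = order[seq_len(tail_i)], adj = adj)
}

# Native/intruder state per tip, as a logical vector indexed by tip number.
tip_native_state <- function(tree, natives) {
  missing_leaves <- setdiff(natives, tree$tip.label)
  if (length(missing_leaves) > 0) {
    stopf("native leaf/leaves not in tree: %s",
          paste(head(missing_leaves, 5), collapse = ", "))
  }
  tree$tip.label %in% natives
}

#' Collapse poorly supported internal edges
#'
#' Contracts every internal edge whose support is below `cutoff`, producing
#' polytomies; edges without a support value are kept. The leaf set is
#' unchanged. Branch lengths are dropped (topological analysis follows).
#'
#' @param tree A `phylo` with optional internal-node labels holding
#'   supports in `[0, 100]`.
#' @param cutoff Support threshold in percent (default 50).
#' @return The collapsed `phylo`.
#' @export
collapse_low_support <- function(tree, cutoff = 50) {
  if (!is.numeric(cutoff) || cutoff < 0 || cutoff > 100) {
    stopf("cutoff must lie in [0, 100]")
  }
  n_tip <- ape::Ntip(tree)
  sup <- node_supports(tree)
  root <- n_tip + 1L
  internal <- (n_tip + 1L):(n_tip + tree$Nnode)
  drop <- internal[!is.na(sup) & sup < cutoff & internal != root]
  if (length(drop) == 0) {
    tree$edge.length <- NULL
    return(tree)
  }
  parent <- parent_vector(tree)
  climb <- function(v) {
    while (v %in% drop) v <- parent[v]
    v
  }
  keep_internal <- setdiff(internal, drop)
  new_id <- integer(n_tip + tree$Nnode)
  new_id[seq_len(n_tip)] <- seq_len(n_tip)
  new_id[keep_internal] <- n_tip + seq_along(keep_internal)
  edges <- matrix(0L, nrow = 0, ncol = 2)
  for (v in c(seq_len(n_tip), keep_internal)) {
    if (v == root) next
    p <- climb(parent[v])
    edges <- rbind(edges, c(new_id[p], new_id[v]))
  }
  out <- list(edge = edges, tip.label = tree$tip.label,
              Nnode = length(keep_internal),
              node.label = tree$node.label[keep_internal - n_tip])
  class(out) <- "phylo"
  out <- ape::reorder.phylo(out, "cladewise")
  out
}

#' Two-state parsimony score of a native/intruder labelling (p-score)
#'
#' Minimum number of state changes of the binary native/intruder character
#' over the unrooted (possibly multifurcating) tree — equivalently the
#' minimum number of edge cuts separating natives from intruders. Computed
#' with Hartigan's generalisation of Fitch parsimony, which is exact on
#' polytomies. A monochromatic tree scores 0.
#'
#' @param tree A `phylo`.
#' @param natives Character vector of native leaf labels.
#' @return Non-negative integer.
#' @examples
#' tr <- ape::read.tree(text = "((E1,E2),(B1,B2));")
#' p_score(tr, c("E1", "E2"))
#' @export
p_score <- function(tree, natives) {
  n_tip <- ape::Ntip(tree)
  state <- tip_native_state(tree, natives)
  if (n_tip <= 1 || all(state) || !any(state)) return(0L)
  ori <- orient_tree(tree, n_tip + 1L)
  n_node <- n_tip + tree$Nnode
  # per-node vote sets as two logical columns (native, intruder)
  set_nat <- logical(n_node); set_int <- logical(n_node)
  set_nat[seq_len(n_tip)] <- state
  set_int[seq_len(n_tip)] <- !state
  children <- split(seq_len(n_node)[ori$parent > 0],
                    ori$parent[ori$parent > 0])
  score <- 0L
  for (v in rev(ori$order)) {
    ch <- children[[as.character(v)]]
    if (is.null(ch)) next
    n_nat <- sum(set_nat[ch]); n_int <- sum(set_int[ch])
    m <- max(n_nat, n_int)
    set_nat[v] <- n_nat == m
    set_int[v] <- n_int == m
    score <- score + length(ch) - m
  }
  as.integer(score)
}

# Sizes of the maximal native-pure clans (subtrees all of whose leaves are
# native), oriented from an intruder leaf so clans are well defined on the
# unrooted tree. Returns integer(0) when there are no natives.
native_group_sizes <- function(tree, natives) {
  n_tip <- ape::Ntip(tree)
  state <- tip_native_state(tree, natives)
  if (!any(state)) return(integer(0))
  if (all(state)) return(sum(state))
  r <- which(!state)[1]
  ori <- orient_tree(tree, r)
  n_node <- n_tip + tree$Nnode
  leaves_below <- integer(n_node)
  natives_below <- integer(n_node)
  leaves_below[seq_len(n_tip)] <- 1L
  natives_below[seq_len(n_tip)] <- as.integer(state)
  for (v in rev(ori$order)) {
    p <- ori$parent[v]
    if (p > 0) {
      leaves_below[p] <- leaves_below[p] + leaves_below[v]
      natives_below[p] <- natives_below[p] + natives_below[v]
    }
  }
  pure <- leaves_below > 0 & natives_below == leaves_below
  pure[r] <- FALSE
  maximal <- pure & !pure[pmax(ori$parent, 1L)]
  maximal[r] <- FALSE
  natives_below[maximal]
}

#' E*: equitability of native dispersal across a tree
#'
#' Shannon equitability of the size distribution of the maximal native-only
#' clans. With group sizes `c1..ck` and `N = sum(ci)`:
#' `E* = -sum((ci/N) * log(ci/N)) / log(N)` for `N >= 2`, and 0 when the
#' natives form a single group or there is a single native. Perfectly
#' grouped natives give 0; natives strictly alternating with intruders give
#' 1; frequent lateral exchange pushes E* towards 1.
#'
#' @inheritParams p_score
#' @return A value in `[0, 1]`, or `NA` when the tree has no native leaf.
#' @export
e_star <- function(tree, natives) {
  sizes <- native_group_sizes(tree, natives)
  if (length(sizes) == 0) return(NA_real_)
  n <- sum(sizes)
  if (n == 1 || length(sizes) == 1) return(0)
  p <- sizes / n
  min(1, -sum(p * log(p)) / log(n))
}

#' Classify one labelled tree as pure, perfect clan, perfect slice or melange
#'
#' `pure`: one category only. `perfect_clan`: a single edge cut isolates
#' exactly the natives. `perfect_slice`: two edge cuts isolate exactly the
#' natives as the middle component, and no single cut does. Otherwise
#' `melange` — natives and intruders are intertwined, the signature of
#' repeated lateral transfer. The report carries [e_star()], [p_score()]
#' and a `trivial` flag for trees with at most one native.
#'
#' @inheritParams p_score
#' @param tree_id Optional identifier copied into the report.
#' @return A one-row tibble: `tree_id`, `classification`, `e_star`,
#'   `p_score`, `n_native`, `n_intruder`, `trivial`.
#' @export
classify_clan <- function(tree, natives, tree_id = NA_character_) {
  n_tip <- ape::Ntip(tree)
  state <- tip_native_state(tree, natives)
  n_nat <- sum(state); n_int <- n_tip - n_nat
  cls <- if (n_int == 0 || n_nat == 0) {
    "pure"
  } else {
    clan_slice_class(tree, state)
  }
  tibble::tibble(
    tree_id = tree_id,
    classification = cls,
    e_star = e_star(tree, tree$tip.label[state]),
    p_score = p_score(tree, tree$tip.label[state]),
    n_native = n_nat, n_intruder = n_int,
    trivial = n_nat <= 1
  )
}

# Decide perfect_clan / perfect_slice / melange for a mixed tree.
clan_slice_class <- function(tree, state) {
  n_tip <- ape::Ntip(tree)
  n_nat <- sum(state)
  r <- which(!state)[1]
  ori <- orient_tree(tree, r)
  n_node <- n_tip + tree$Nnode
  leaves_below <- integer(n_node)
  natives_below <- integer(n_node)
  leaves_below[seq_len(n_tip)] <- 1L
  natives_below[seq_len(n_tip)] <- as.integer(state)
  for (v in rev(ori$order)) {
    p <- ori$parent[v]
    if (p > 0) {
      leaves_below[p] <- leaves_below[p] + leaves_below[v]
      natives_below[p] <- natives_below[p] + natives_below[v]
    }
  }
  intr_below <- leaves_below - natives_below
  candidates <- setdiff(which(natives_below == n_nat), r)
  if (any(intr_below[candidates] == 0)) return("perfect_clan")
  # Both cut edges must be nested under the intruder rooting (otherwise the
  # middle component contains the intruder root), so a slice exists iff some
  # clan v1 holding all natives has all its intruders under one strict
  # descendant v2.
  is_descendant <- function(v2, v1) {
    v <- v2
    while (v != r && v != 0) {
      v <- ori$parent[v]
      if (v == v1) return(TRUE)
    }
    FALSE
  }
  v2_candidates <- which(natives_below == 0 & seq_len(n_node) != r)
  for (v1 in candidates) {
    need <- intr_below[v1]
    for (v2 in v2_candidates) {
      if (v2 != v1 && intr_below[v2] == need && is_descendant(v2, v1)) {
        return("perfect_slice")
      }
    }
  }
  "melange"
}

#' Resolve native leaves of a tree from an annotation table
#'
#' @param tree A `phylo`.
#' @param annotations Annotation table covering every leaf.
#' @param values Values of `field` that define the native category (e.g.
#'   `paste0("EC", 1:30)` for E. coli, or `"PATH"` with
#'   `field = "pathogenicity"`).
#' @param field Annotation column to match (default `"taxon_class"`).
#' @param remap Optional named character vector applied to the field first
#'   (e.g. to re-badge Shigella-like strains as E. coli).
#' @return Character vector of native leaf labels.
#' @export
native_leaves <- function(tree, annotations, values, field = "taxon_class",
                          remap = NULL) {
  v <- annotation_lookup(tree$tip.label, annotations, field)
  if (!is.null(remap)) {
    hit <- v %in% names(remap)
    v[hit] <- remap[v[hit]]
  }
  tree$tip.label[v %in% values]
}

#' Classify every tree of a forest
#'
#' Applies [classify_clan()] across a forest for a two-category labelling
#' derived from the annotation table, optionally after collapsing poorly
#' supported branches.
#'
#' @param forest A `gene_forest` (or list of `phylo`).
#' @param annotations Annotation table covering every leaf of every tree.
#' @inheritParams native_leaves
#' @param support_cutoff If non-`NULL`, internal edges with support below
#'   this percent are collapsed first (see [collapse_low_support()]).
#' @return Tibble with one [classify_clan()] row per tree.
#' @export
classify_forest <- function(forest, annotations, values,
                            field = "taxon_class", remap = NULL,
                            support_cutoff = NULL) {
  forest <- as_gene_forest(forest)
  purrr::imap_dfr(forest, function(tree, id) {
    if (!is.null(support_cutoff)) tree <- collapse_low_support(tree, support_cutoff)
    nat <- native_leaves(tree, annotations, values, field, remap)
    classify_clan(tree, nat, tree_id = id)
  })
}

#' Summarise a classified forest
#'
#' Counts per classification (with trivial clans/slices — at most one
#' native — tallied separately), percentages of the forest total (1
#' decimal), and the mean E* over melange trees (the paper-style
#' "E* melange"; set `melange_only = FALSE` to average over all non-pure
#' trees instead).
#'
#' @param report Output of [classify_forest()].
#' @param melange_only Average E* over melange trees only (default) or over
#'   all non-pure trees.
#' @return A list with `counts` (one row per classification: `n`,
#'   `n_trivial`, `pct`), `n_trees`, and `mean_e_star_melange`.
#' @export
forest_summary <- function(report, melange_only = TRUE) {
  levels <- c("pure", "perfect_clan", "perfect_slice", "melange")
  counts <- report |>
    dplyr::mutate(classification = factor(.data$classification, levels = levels)) |>
    dplyr::group_by(.data$classification, .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(), n_trivial = sum(.data$trivial),
                     .groups = "drop") |>
    dplyr::mutate(pct = if (nrow(report) > 0)
      round_half_up(100 * .data$n / nrow(report), 1) else 0)
  e_pool <- if (melange_only) {
    report$e_star[report$classification == "melange"]
  } else {
    report$e_star[report$classification != "pure"]
  }
  list(counts = counts, n_trees = nrow(report),
       mean_e_star_melange = if (length(e_pool) > 0) mean(e_pool, na.rm = TRUE)
       else NA_real_)
}

#' Candidate mobile modules of pathogenicity
#'
#' Groups of gene trees that (i) contain at least one mobile-genetic-element
#' leaf, (ii) whose cellular leaves are all from pathogenic hosts (the
#' p-score is 0 when PATH are the natives among cellular sequences), and
#' (iii) that share an identical strain presence/absence profile. Such
#' groups behave like gene sets co-inherited by a mobile element and found
#' only in pathogens.
#'
#' @param forest A `gene_forest`.
#' @param annotations Annotation table.
#' @param strains Strain universe for the presence/absence vector; default
#'   all `EC*` taxon classes seen in the annotations.
#' @param support_cutoff Optional support collapsing before evaluation
#'   (does not change leaf content; kept for protocol symmetry).
#' @param min_group_size Minimum trees per reported group (default 2).
#' @return Tibble `(group_id, tree_id, strain_profile)`.
#' @export
find_mobile_modules <- function(forest, annotations, strains = NULL,
                                support_cutoff = NULL, min_group_size = 2) {
  forest <- as_gene_forest(forest)
  strains <- strains %||%
    sort(unique(grep("^EC", annotations$taxon_class, value = TRUE)))
  rows <- purrr::imap_dfr(forest, function(tree, id) {
    taxa <- annotation_lookup(tree$tip.label, annotations, "taxon_class")
    path <- annotation_lookup(tree$tip.label, annotations, "pathogenicity")
    cellular <- taxa != "MGE"
    present <- strains %in% taxa
    tibble::tibble(
      tree_id = id,
      has_mge = any(taxa == "MGE"),
      all_path = sum(cellular) > 0 && all(path[cellular] == "PATH"),
      strain_profile = paste(strains[present], collapse = ",")
    )
  })
  eligible <- rows |>
    dplyr::filter(.data$has_mge, .data$all_path, .data$strain_profile != "")
  groups <- eligible |>
    dplyr::group_by(.data$strain_profile) |>
    dplyr::filter(dplyr::n() >= min_group_size) |>
    dplyr::ungroup()
  if (nrow(groups) == 0) {
    return(tibble::tibble(group_id = character(0), tree_id = character(0),
                          strain_profile = character(0)))
  }
  keys <- sort(unique(groups$strain_profile))
  groups |>
    dplyr::mutate(group_id = sprintf("M%03d", match(.data$strain_profile, keys))) |>
    dplyr::arrange(.data$group_id, .data$tree_id) |>
    dplyr::select("group_id", "tree_id", "strain_profile")
}
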