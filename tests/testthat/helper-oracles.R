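# Independent oracles, written before the tests that use them. Each one
# recomputes a quantity the package computes, by a different (usually
# brute-force) route, using only base R and ape's tree plumbing.

# ---- union-find components ------------------------------------------------

# Connected components of an undirected graph given as node ids and an
# edge list (two parallel vectors). Returns a named membership vector.
oracle_components <- function(nodes, from, to) {
  parent <- seq_along(nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  fi <- match(from, nodes)
  ti <- match(to, nodes)
  for (k in seq_along(fi)) {
    a <- find(fi[k]); b <- find(ti[k])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  setNames(match(roots, unique(roots)), nodes)
}

# ---- brute-force two-state parsimony --------------------------------------

# Minimum number of edges whose endpoints disagree, over all assignments of
# the two states to internal nodes; leaf states are fixed by membership in
# `natives`. Exponential in the number of internal nodes: use small trees.
oracle_pscore <- function(tree, natives) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  leaf_state <- as.integer(tree$tip.label %in% natives)
  best <- Inf
  for (code in 0:(2^n_int - 1)) {
    int_state <- as.integer(intToBits(code))[seq_len(n_int)]
    state <- c(leaf_state, int_state)
    cost <- sum(state[tree$edge[, 1]] != state[tree$edge[, 2]])
    best <- min(best, cost)
  }
  best
}

# ---- quartet topology via subtree extraction ------------------------------

# Induced split of four leaves, ignoring supports: restrict with
# ape::keep.tip, unroot, and read off the single internal edge. Returns a
# canonical string "a,b|c,d" (each side sorted, sides ordered), or NA for a
# star.
oracle_quartet_split <- function(tree, four) {
  sub <- ape::unroot(ape::keep.tip(tree, four))
  internal <- sub$edge[, 2] > 4
  if (!any(internal)) return(NA_character_)
  child <- sub$edge[internal, 2][1]
  # tips below `child` in the rooted representation of the unrooted tree
  below <- child
  repeat {
    kids <- sub$edge[sub$edge[, 1] %in% below[below > 4], 2]
    grown <- union(below, kids)
    if (length(grown) == length(below)) break
    below <- grown
  }
  side <- sort(sub$tip.label[below[below <= 4]])
  other <- sort(setdiff(sub$tip.label, side))
  paste(sapply(list(side, other)[order(c(side[1], other[1]))],
               paste, collapse = ","), collapse = "|")
}

canonical_split <- function(pair_a, pair_b) {
  a <- sort(pair_a); b <- sort(pair_b)
  paste(sapply(list(a, b)[order(c(a[1], b[1]))], paste, collapse = ","),
        collapse = "|")
}

# ---- shortest-path betweenness by path counting ---------------------------

# Node betweenness on an unweighted undirected graph from its adjacency
# matrix: BFS distances, dynamic-programming geodesic counts, then the
# classic pair-sum. Each unordered pair counted once, endpoints excluded.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0; sigma[s, s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] > 0)) {
          if (is.infinite(d[s, w])) {
            d[s, w] <- d[s, v] + 1
            nxt <- c(nxt, w)
          }
          if (d[s, w] == d[s, v] + 1) {
            sigma[s, w] <- sigma[s, w] + sigma[s, v]
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (is.infinite(d[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (d[s, v] + d[v, t] == d[s, t]) {
        btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  btw
}

# ---- articulation points by deletion --------------------------------------

n_graph_components <- function(adj) {
  n <- nrow(adj)
  if (n == 0) return(0L)
  seen <- rep(FALSE, n)
  comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    frontier <- s; seen[s] <- TRUE
    while (length(frontier) > 0) {
      nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ] > 0))))
      nxt <- nxt[!seen[nxt]]
      seen[nxt] <- TRUE
      frontier <- nxt
    }
  }
  comps
}

oracle_articulation <- function(adj) {
  n <- nrow(adj)
  base <- n_graph_components(adj)
  vapply(seq_len(n), function(v) {
    # deleting v removes one vertex; v is a cut vertex iff the remaining
    # graph has strictly more components than the original graph had
    n_graph_components(adj[-v, -v, drop = FALSE]) > base
  }, logical(1))
}

# ---- clan / slice classification by exhaustive cut enumeration ------------

# Leaf sets of the connected components of the tree after deleting the
# edges indexed by `drop` (row indices into tree$edge).
tree_cut_leafsets <- function(tree, drop) {
  n_node <- length(tree$tip.label) + tree$Nnode
  keep <- setdiff(seq_len(nrow(tree$edge)), drop)
  memb <- oracle_components(seq_len(n_node),
                            tree$edge[keep, 1], tree$edge[keep, 2])
  tips <- seq_along(tree$tip.label)
  split(tree$tip.label, memb[tips])
}

# Classify a native set on an unrooted tree by trying every 1-cut and every
# 2-cut: "pure" when one category is absent, "perfect_clan" when some single
# cut isolates exactly the natives, "perfect_slice" when some pair of cuts
# does, otherwise "melange".
oracle_classify <- function(tree, natives) {
  natives <- intersect(tree$tip.label, natives)
  if (length(natives) == 0 || length(natives) == length(tree$tip.label)) {
    return("pure")
  }
  target <- sort(natives)
  hits_target <- function(leafsets) {
    any(vapply(leafsets, function(ls) identical(sort(ls), target), logical(1)))
  }
  n_edge <- nrow(tree$edge)
  for (e in seq_len(n_edge)) {
    if (hits_target(tree_cut_leafsets(tree, e))) return("perfect_clan")
  }
  for (e1 in seq_len(n_edge - 1)) for (e2 in (e1 + 1):n_edge) {
    if (hits_target(tree_cut_leafsets(tree, c(e1, e2)))) {
      return("perfect_slice")
    }
  }
  "melange"
}

# ---- shared helpers -------------------------------------------------------

# Random unrooted tree with the given labels (no supports).
random_unrooted_tree <- function(labels) {
  ape::unroot(ape::rtree(length(labels), tip.label = sample(labels)))
}

# Minimal annotation row block for strain sequences named like the leaf.
strain_annotations <- function(leaves, strains = leaves,
                               pathogenicity = "PATH") {
  tibble::tibble(
    sequence_id = leaves,
    genome_id = strains,
    taxon_class = strains,
    pathogenicity = rep_len(pathogenicity, length(leaves)),
    disease = "none",
    cog_category = "S",
    mge_class = "none")
}

# A tiny hit-table row in the package's column order.
hit_row <- function(q, s, ident, ev = 1e-50, bits = 500) {
  tibble::tibble(query = q, subject = s, identity_pct = ident,
                 aln_length = 100L, mismatches = 0L, gap_opens = 0L,
                 q_start = 1L, q_end = 100L, s_start = 1L, s_end = 100L,
                 evalue = ev, bitscore = bits, self = q == s)
}
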