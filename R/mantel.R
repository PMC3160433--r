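#' Mantel permutation test for group-structured distances
#'
#' Tests whether distances between strains of different groups (e.g. PATH
#' vs NON-PATH) are larger than distances within groups. The statistic is
#' the Pearson correlation `r` between the off-diagonal distances and a
#' binary design matrix (0 within group, 1 between groups); the p-value is
#' one-tailed, from random permutations of the group labels across strains.
#' Because permuting labels leaves the number of between-group pairs
#' unchanged, the permuted correlations reduce to sums over the permuted
#' between-group cells, which is computed in a single matrix product.
#'
#' @param dist A [taxon_dist()] (complete) or symmetric matrix.
#' @param groups Named character/factor vector, strain -> group, with at
#'   least two strains per group.
#' @param n_permutations Number of label permutations (default 9999).
#' @param seed Optional RNG seed.
#' @return A `pq_mantel` object: `statistic` (r), `p_value`,
#'   `n_permutations`, `n_taxa`, `alternative`.
#' @examples
#' d <- matrix(c(0, .1, .8, .1, 0, .9, .8, .9, 0), 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' mantel_test(d, c(a = "G1", b = "G1", c = "G2"),
#'             n_permutations = 99, seed = 1)
#' @export
mantel_test <- function(dist, groups, n_permutations = 9999, seed = NULL) {
  if (inherits(dist, "taxon_dist")) {
    if (any(dist$missing)) stopf("distance matrix has missing pairs; impute first")
    m <- dist$values
  } else {
    m <- as.matrix(dist)
  }
  taxa <- rownames(m)
  if (is.null(taxa)) stopf("distance matrix must have taxon names")
  g <- groups[taxa]
  if (anyNA(g)) {
    stopf("group label missing for: %s",
          paste(head(taxa[is.na(g)], 5), collapse = ", "))
  }
  if (any(table(g) < 2)) stopf("each group needs at least two strains")
  n <- length(taxa)
  ut <- upper.tri(m)
  x <- m[ut]
  if (sd(x) == 0) stopf("constant distance matrix: r is undefined")
  pair_i <- row(m)[ut]
  pair_j <- col(m)[ut]
  y <- as.numeric(g[pair_i] != g[pair_j])
  r_obs <- cor(x, y)
  if (!is.null(seed)) set.seed(seed)
  xc <- x - mean(x)
  sy <- sd(y)
  denom <- (length(x) - 1) * sd(x) * sy
  r_perm <- numeric(n_permutations)
  for (p in seq_len(n_permutations)) {
    gp <- g[sample.int(n)]
    yp <- gp[pair_i] != gp[pair_j]
    r_perm[p] <- sum(xc[yp]) / denom
  }
  p_value <- (1 + sum(r_perm >= r_obs)) / (n_permutations + 1)
  structure(list(statistic = r_obs, p_value = p_value,
                 n_permutations = n_permutations, n_taxa = n,
                 groups = g,
                 alternative = "between-group distances exceed within-group"),
            class = "pq_mantel")
}

#' @export
print.pq_mantel <- function(x, ...) {
  cat(sprintf("Mantel test (one-tailed, %d permutations): r = %.4f, p = %.4g\n",
              x$n_permutations, x$statistic, x$p_value))
  invisible(x)
}

#' Compare mean pairwise PQ distances of two strain-pair sets
#'
#' Welch two-sample t-test over the off-diagonal distances of two distance
#' matrices on the same strains (e.g. core vs shell gene sets). Pairwise
#' distances are not independent observations, so read the p-value as a
#' descriptive index rather than an exact error rate.
#'
#' @param dist_a,dist_b [taxon_dist()] objects or matrices.
#' @return A `htest` from [stats::t.test()] plus means as `estimate`.
#' @export
compare_distance_sets <- function(dist_a, dist_b) {
  va <- as.matrix(dist_a); vb <- as.matrix(dist_b)
  stats::t.test(va[upper.tri(va)], vb[upper.tri(vb)], var.equal = FALSE)
}
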