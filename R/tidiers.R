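# Broom-style tidiers for the package's result objects.

#' Tidy a PQ strain-pair matrix
#'
#' @param x A `pq_matrix`.
#' @param ... Unused.
#' @return One row per unordered strain pair: co-occurrence and same-clan
#'   quartet counts and the same-clan frequency (`NA` when never
#'   co-sampled).
#' @export
tidy.pq_matrix <- function(x, ...) {
  ut <- which(upper.tri(x$frequency), arr.ind = TRUE)
  tibble::tibble(
    strain_a = x$strains[ut[, 1]],
    strain_b = x$strains[ut[, 2]],
    cooccurrence = x$cooccurrence[ut],
    same_clan = x$same_clan[ut],
    frequency = x$frequency[ut]
  )
}

#' @rdname tidy.pq_matrix
#' @export
glance.pq_matrix <- function(x, ...) {
  f <- x$frequency[upper.tri(x$frequency)]
  tibble::tibble(
    n_strains = length(x$strains),
    n_pairs = choose(length(x$strains), 2),
    n_pairs_observed = sum(!is.na(f)),
    n_trees_sampled = x$n_trees_sampled,
    mean_frequency = mean(f, na.rm = TRUE)
  )
}

#' Tidy a taxon distance matrix
#'
#' @param x A `taxon_dist`.
#' @param ... Unused.
#' @return One row per unordered pair: `taxon_a`, `taxon_b`, `distance`,
#'   `imputed`.
#' @export
tidy.taxon_dist <- function(x, ...) {
  ut <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(
    taxon_a = x$taxa[ut[, 1]],
    taxon_b = x$taxa[ut[, 2]],
    distance = x$values[ut],
    imputed = x$missing[ut]
  )
}

#' Tidy a Mantel test result
#'
#' @param x A `pq_mantel`.
#' @param ... Unused.
#' @return A one-row tibble with `estimate` (r), `p.value`, permutation
#'   count and sample size.
#' @export
tidy.pq_mantel <- function(x, ...) {
  tibble::tibble(
    estimate = x$statistic,
    p.value = x$p_value,
    n_permutations = x$n_permutations,
    n_taxa = x$n_taxa,
    alternative = x$alternative
  )
}

#' @rdname tidy.pq_mantel
#' @export
glance.pq_mantel <- function(x, ...) tidy(x)

#' Tidy a genome network
#'
#' @param x A `genome_network`.
#' @param ... Unused.
#' @return The edge table (shared-family counts and display weights).
#' @export
tidy.genome_network <- function(x, ...) {
  x$edges |>
    dplyr::mutate(n_shared_families = lengths(.data$shared_families)) |>
    dplyr::select("genome_a", "genome_b", "shared_count", "display_weight",
                  "n_shared_families")
}

#' @rdname tidy.genome_network
#' @export
glance.genome_network <- function(x, ...) {
  tibble::tibble(
    band_lo = x$band[1], band_hi = x$band[2],
    n_genomes = nrow(x$nodes), n_edges = nrow(x$edges),
    n_shared_families = dplyr::n_distinct(x$band_families$family_id)
  )
}

#' Tidy a gene network
#'
#' @param x A `gene_network`.
#' @param ... Passed on to [component_metrics()].
#' @return The per-component metric table.
#' @export
tidy.gene_network <- function(x, ...) component_metrics(x, ...)

#' @rdname tidy.gene_network
#' @export
glance.gene_network <- function(x, ...) {
  tibble::tibble(
    n_sequences = igraph::vcount(x$graph),
    n_edges = igraph::ecount(x$graph),
    n_components = x$n_components
  )
}
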