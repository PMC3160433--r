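# Gene-family clustering from homology hits: single linkage over hit pairs,
# optionally restricted to reciprocal best hits ("true BBH").

#' Reciprocal best hits between genomes
#'
#' For every query sequence and target genome, the best-scoring subject is
#' the hit with the highest bit score, ties broken by lower e-value, then by
#' lexicographically smaller subject id. An unordered pair `{a, b}` is a
#' reciprocal best hit when `b` is `a`'s best subject in `b`'s genome and
#' `a` is `b`'s best subject in `a`'s genome. Self-hits never qualify.
#'
#' @param hits Hit tibble as returned by [read_hits()].
#' @param annotations Annotation table mapping every sequence to a genome.
#' @return Tibble with columns `seq_a`, `seq_b` (sorted within row), one row
#'   per reciprocal pair.
#' @export
reciprocal_best_hits <- function(hits, annotations) {
  hits <- dplyr::filter(hits, .data$query != .data$subject)
  ids <- unique(c(hits$query, hits$subject))
  unmapped <- setdiff(ids, annotations$sequence_id)
  if (length(unmapped) > 0) {
    stopf("sequence(s) lack a genome mapping: %s",
          paste(head(unmapped, 5), collapse = ", "))
  }
  genome_of <- annotation_lookup(ids, annotations, "genome_id")
  best <- hits |>
    dplyr::mutate(subject_genome = unname(genome_of[.data$subject])) |>
    dplyr::group_by(.data$query, .data$subject_genome) |>
    dplyr::arrange(dplyr::desc(.data$bitscore), .data$evalue, .data$subject,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("query", "subject")
  forward <- paste(best$query, best$subject, sep = "\r")
  backward <- paste(best$subject, best$query, sep = "\r")
  reciprocal <- best[forward %in% backward, ]
  out <- pair_sort(reciprocal$query, reciprocal$subject)
  dplyr::distinct(tibble::tibble(seq_a = out$first, seq_b = out$second))
}

# Collapse the two directions of each hit pair to one undirected edge,
# keeping the better statistics (max identity, min e-value, max bit score).
undirected_hit_edges <- function(hits) {
  hits <- dplyr::filter(hits, .data$query != .data$subject)
  p <- pair_sort(hits$query, hits$subject)
  tibble::tibble(seq_a = p$first, seq_b = p$second,
                 identity_pct = hits$identity_pct,
                 evalue = hits$evalue, bitscore = hits$bitscore) |>
    dplyr::group_by(.data$seq_a, .data$seq_b) |>
    dplyr::summarise(identity_pct = max(.data$identity_pct),
                     evalue = min(.data$evalue),
                     bitscore = max(.data$bitscore), .groups = "drop")
}

#' Cluster sequences into gene families by single linkage
#'
#' Families are the connected components of the graph whose edges are hit
#' pairs passing an e-value ceiling and an identity floor. In `false_bbh`
#' mode any passing hit pair is an edge; in `true_bbh` mode only reciprocal
#' best-hit pairs (see [reciprocal_best_hits()]) are edges. When the two
#' directions of a hit disagree, the pair passes if its better direction
#' passes. Sequences named in `annotations` but absent from all passing
#' edges become singleton families, so families always partition the
#' sequence universe.
#'
#' @param hits Hit tibble ([read_hits()]).
#' @param mode `"false_bbh"` (default) or `"true_bbh"`.
#' @param identity_min Minimum percent identity for an edge (default 0; the
#'   phylogenetic-forest families use 70).
#' @param evalue_max E-value ceiling for an edge (default `1e-20`).
#' @param annotations Required for `true_bbh` (genome mapping); otherwise
#'   optional, used only to complete the universe with singletons.
#' @return Tibble `(family_id, sequence_id)`, one row per sequence, carrying
#'   attributes `mode`, `identity_min`, `evalue_max`.
#' @examples
#' hits <- tibble::tibble(
#'   query = c("a", "b"), subject = c("b", "c"),
#'   identity_pct = c(90, 85), evalue = c(1e-40, 1e-30), bitscore = c(200, 150)
#' )
#' cluster_families(hits)
#' @export
cluster_families <- function(hits, mode = c("false_bbh", "true_bbh"),
                             identity_min = 0, evalue_max = 1e-20,
                             annotations = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(evalue_max) || evalue_max <= 0) {
    stopf("evalue_max must be a positive number")
  }
  if (identity_min < 0 || identity_min > 100) {
    stopf("identity_min must lie in [0, 100]")
  }
  edges <- undirected_hit_edges(hits)
  if (mode == "true_bbh") {
    if (is.null(annotations)) stopf("true_bbh mode requires annotations")
    rbh <- reciprocal_best_hits(hits, annotations)
    edges <- dplyr::semi_join(edges, rbh, by = c("seq_a", "seq_b"))
  }
  edges <- dplyr::filter(edges, .data$evalue <= evalue_max,
                         .data$identity_pct >= identity_min)
  universe <- unique(c(hits$query, hits$subject,
                       if (!is.null(annotations)) annotations$sequence_id))
  g <- igraph::graph_from_data_frame(
    edges[, c("seq_a", "seq_b")], directed = FALSE,
    vertices = data.frame(name = universe)
  )
  comp <- igraph::components(g)$membership
  members <- split(names(comp), comp)
  ord <- order(-lengths(members),
               vapply(members, function(m) min(m), character(1)))
  members <- members[ord]
  fam <- tibble::tibble(
    family_id = rep(sprintf("F%05d", seq_along(members)), lengths(members)),
    sequence_id = unlist(lapply(members, sort), use.names = FALSE)
  )
  attr(fam, "mode") <- mode
  attr(fam, "identity_min") <- identity_min
  attr(fam, "evalue_max") <- evalue_max
  fam
}

#' Summarise gene families
#'
#' @param families Output of [cluster_families()].
#' @param annotations Optional annotation table; adds per-taxon-class member
#'   counts to each family.
#' @return One row per family: size and, when annotations are given, counts
#'   of members per taxon class.
#' @export
family_summary <- function(families, annotations = NULL) {
  base <- families |>
    dplyr::count(.data$family_id, name = "n_members")
  if (is.null(annotations)) return(base)
  cls <- families |>
    dplyr::left_join(annotations[, c("sequence_id", "taxon_class")],
                     by = "sequence_id") |>
    dplyr::count(.data$family_id, .data$taxon_class) |>
    tidyr::pivot_wider(names_from = "taxon_class", values_from = "n",
                       values_fill = 0L, names_prefix = "n_")
  dplyr::left_join(base, cls, by = "family_id")
}
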