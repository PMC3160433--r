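# Identity-sliced genome networks: genomes as nodes, edges weighted by the
# number of gene families the two genomes share within an identity band.

#' Dominant COG category of a set of sequences
#'
#' Modal single-letter category; ties are broken in favour of `L`
#' (replication and repair, the signature of transfer machinery), then
#' alphabetically. `X` wins only when unknowns strictly dominate or tie
#' without a competing earlier letter.
#'
#' @param categories Character vector of single-letter categories.
#' @return One category letter.
#' @export
dominant_category <- function(categories) {
  if (length(categories) == 0) return("X")
  tab <- table(categories)
  top <- names(tab)[tab == max(tab)]
  if ("L" %in% top) "L" else min(top)
}

#' Build an identity-sliced genome network
#'
#' Nodes are genomes; an edge joins two genomes for every gene family with
#' members in both, provided the *maximum* cross-genome member-pair identity
#' falls inside `identity_band`. Edge weight for display is the inverse of
#' the shared-family count, so strongly overlapping genomes sit close in a
#' spring layout.
#'
#' @param families Family membership tibble ([cluster_families()]).
#' @param hits Hit tibble; provides the member-pair identities.
#' @param annotations Annotation table (genome and taxon class per sequence).
#' @param identity_band Numeric `c(lo, hi)` percent identity band, e.g.
#'   `c(100, 100)` for candidate recent transfers or `c(90, 99)` for a
#'   slightly more ancient slice.
#' @return A `genome_network`: list with `nodes` (genome, taxon_class),
#'   `edges` (genome_a, genome_b, shared_count, display_weight,
#'   shared_families list-column), `family_members`, and `band`.
#' @export
build_genome_network <- function(families, hits, annotations,
                                 identity_band = c(100, 100)) {
  if (length(identity_band) != 2 || identity_band[1] > identity_band[2]) {
    stopf("identity_band must be c(lo, hi) with lo <= hi")
  }
  ann <- annotations[, c("sequence_id", "genome_id", "taxon_class", "cog_category")]
  fam <- dplyr::inner_join(families, ann, by = "sequence_id")
  edges <- undirected_hit_edges(hits)
  fam_a <- fam |> dplyr::select(seq_a = "sequence_id", family_id_a = "family_id",
                                genome_a = "genome_id")
  fam_b <- fam |> dplyr::select(seq_b = "sequence_id", family_id_b = "family_id",
                                genome_b = "genome_id")
  within <- edges |>
    dplyr::inner_join(fam_a, by = "seq_a") |>
    dplyr::inner_join(fam_b, by = "seq_b") |>
    dplyr::filter(.data$family_id_a == .data$family_id_b,
                  .data$genome_a != .data$genome_b)
  gp <- pair_sort(within$genome_a, within$genome_b)
  within$genome_a <- gp$first
  within$genome_b <- gp$second
  band_pairs <- within |>
    dplyr::group_by(family_id = .data$family_id_a, .data$genome_a, .data$genome_b) |>
    dplyr::summarise(max_identity = max(.data$identity_pct), .groups = "drop") |>
    dplyr::filter(.data$max_identity >= identity_band[1],
                  .data$max_identity <= identity_band[2])
  net_edges <- band_pairs |>
    dplyr::group_by(.data$genome_a, .data$genome_b) |>
    dplyr::summarise(shared_count = dplyr::n_distinct(.data$family_id),
                     shared_families = list(sort(unique(.data$family_id))),
                     .groups = "drop") |>
    dplyr::mutate(display_weight = 1 / .data$shared_count)
  nodes <- ann |>
    dplyr::distinct(genome = .data$genome_id, .data$taxon_class)
  structure(
    list(nodes = nodes, edges = net_edges,
         family_members = fam |> dplyr::rename(genome = "genome_id"),
         band = identity_band,
         band_families = band_pairs),
    class = "genome_network"
  )
}

#' @export
print.genome_network <- function(x, ...) {
  cat(sprintf("<genome_network> band [%g, %g]%%: %d genomes, %d edges, %d shared families\n",
              x$band[1], x$band[2], nrow(x$nodes), nrow(x$edges),
              dplyr::n_distinct(x$band_families$family_id)))
  invisible(x)
}

# Sequences supporting the band: members of a band-counted family residing
# in a genome that shares that family with someone in the band.
band_sequences <- function(network) {
  long <- network$band_families |>
    tidyr::pivot_longer(c("genome_a", "genome_b"),
                        values_to = "genome", names_to = NULL) |>
    dplyr::distinct(.data$family_id, .data$genome)
  dplyr::inner_join(network$family_members, long,
                    by = c("family_id", "genome")) |>
    dplyr::distinct(.data$family_id, .data$sequence_id, .data$genome,
                    .data$taxon_class, .data$cog_category)
}

#' Add percentage-of-column-total columns to a count table
#'
#' @param counts A data frame of per-category counts.
#' @param count_cols Names of count columns to convert; each gains a
#'   `pct_<name>` companion, rounded to 1 decimal of the column total.
#' @return The augmented tibble.
#' @export
category_shares <- function(counts, count_cols) {
  counts <- tibble::as_tibble(counts)
  for (cc in count_cols) {
    total <- sum(counts[[cc]])
    counts[[paste0("pct_", cc)]] <-
      if (total > 0) round_half_up(100 * counts[[cc]] / total, 1) else 0
  }
  counts
}

#' Functional-category summary of a genome network
#'
#' Counts, per COG category, the shared sequences and shared gene families
#' in the network's identity band, with each category's percentage of the
#' column total. A family's category is the dominant category of its
#' members ([dominant_category()]); `X` absorbs unknowns.
#'
#' @param network A `genome_network`.
#' @return Tibble `(cog_category, n_sequences, n_families, pct_n_sequences,
#'   pct_n_families)`.
#' @export
summarize_categories <- function(network) {
  seqs <- band_sequences(network)
  seq_counts <- seqs |>
    dplyr::distinct(.data$sequence_id, .data$cog_category) |>
    dplyr::count(.data$cog_category, name = "n_sequences")
  fam_cat <- network$family_members |>
    dplyr::semi_join(network$band_families, by = "family_id") |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(cog_category = dominant_category(.data$cog_category),
                     .groups = "drop")
  fam_counts <- dplyr::count(fam_cat, .data$cog_category, name = "n_families")
  out <- dplyr::full_join(seq_counts, fam_counts, by = "cog_category") |>
    dplyr::mutate(dplyr::across(c("n_sequences", "n_families"),
                                ~ tidyr::replace_na(.x, 0L))) |>
    dplyr::arrange(.data$cog_category)
  category_shares(out, c("n_sequences", "n_families"))
}

#' Candidate recently transferred families between cells and mobile elements
#'
#' Expands every edge joining a cellular genome to a mobile genetic element
#' into one record per shared family. Built for the 100%-identity slice,
#' where shared families are candidates for recent lateral transfer, but
#' works on any band.
#'
#' @param network A `genome_network`.
#' @return Tibble `(cellular_genome, mobile_element, family_id,
#'   cog_category)`, sorted by genome pair then family.
#' @export
find_recent_transfer_candidates <- function(network) {
  taxon_of <- setNames(network$nodes$taxon_class, network$nodes$genome)
  fam_cat <- network$family_members |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(cog_category = dominant_category(.data$cog_category),
                     .groups = "drop")
  out <- network$edges |>
    dplyr::mutate(mge_a = taxon_of[.data$genome_a] == "MGE",
                  mge_b = taxon_of[.data$genome_b] == "MGE") |>
    dplyr::filter(xor(.data$mge_a, .data$mge_b)) |>
    dplyr::mutate(cellular_genome = unname(ifelse(.data$mge_a, .data$genome_b, .data$genome_a)),
                  mobile_element = unname(ifelse(.data$mge_a, .data$genome_a, .data$genome_b))) |>
    dplyr::select("cellular_genome", "mobile_element", "shared_families") |>
    tidyr::unnest_longer("shared_families", values_to = "family_id") |>
    dplyr::left_join(fam_cat, by = "family_id") |>
    dplyr::arrange(.data$cellular_genome, .data$mobile_element, .data$family_id)
  tibble::as_tibble(out)
}

#' Dominant function of each genome-network edge
#'
#' The modal COG category over the sequences the two genomes share on that
#' edge (the members, in either endpoint genome, of the edge's shared
#' families), with the [dominant_category()] tie rule.
#'
#' @param network A `genome_network`.
#' @return The edge tibble with a `dominant_category` column.
#' @export
dominant_edge_function <- function(network) {
  members <- network$family_members
  cat_of <- function(fams, ga, gb) {
    m <- members[members$family_id %in% fams & members$genome %in% c(ga, gb), ]
    dominant_category(m$cog_category)
  }
  network$edges |>
    dplyr::mutate(dominant_category = purrr::pmap_chr(
      list(.data$shared_families, .data$genome_a, .data$genome_b), cat_of))
}

#' Convert a genome network to an igraph graph
#'
#' Node attribute `taxon_class`; edge attributes `shared_count` and
#' `display_weight` (as `weight`).
#'
#' @param network A `genome_network`.
#' @return An `igraph` graph.
#' @export
as_igraph_genome <- function(network) {
  igraph::graph_from_data_frame(
    network$edges |>
      dplyr::transmute(from = .data$genome_a, to = .data$genome_b,
                       shared_count = .data$shared_count,
                       weight = .data$display_weight),
    directed = FALSE,
    vertices = network$nodes |> dplyr::rename(name = "genome")
  )
}

#' Export a genome network as GraphML
#'
#' @param network A `genome_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_graphml <- function(network, path) {
  igraph::write_graph(as_igraph_genome(network), path, format = "graphml")
  invisible(path)
}
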