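# Sequence-level gene networks: nodes are sequences, edges are homology
# relations; each connected component corresponds to one gene family whose
# topology records its evolutionary mode (clique-like conservation vs
# community structure and bridges left by divergence, fusion or transfer).

#' Build a gene network from homology hits
#'
#' Nodes are sequences; an undirected edge joins two sequences when a hit
#' between them passes the e-value ceiling and identity floor (better
#' direction wins when the two directions disagree). The defaults mirror
#' the permissive family definition used for visual triage: e-value below
#' `1e-20`, identity above 30%, no reciprocal-best restriction.
#'
#' @param hits Hit tibble ([read_hits()]).
#' @param annotations Optional annotation table; tags nodes with taxon class.
#' @param identity_min Minimum percent identity (default 30).
#' @param evalue_max E-value ceiling (default `1e-20`).
#' @return A `gene_network`: list with `graph` (igraph), `nodes` tibble
#'   (sequence_id, taxon_class, component_id) and `n_components`.
#' @export
build_gene_network <- function(hits, annotations = NULL,
                               identity_min = 30, evalue_max = 1e-20) {
  edges <- undirected_hit_edges(hits) |>
    dplyr::filter(.data$evalue <= evalue_max,
                  .data$identity_pct >= identity_min)
  universe <- unique(c(hits$query, hits$subject))
  g <- igraph::graph_from_data_frame(
    edges |> dplyr::select(from = "seq_a", to = "seq_b",
                           "identity_pct", "evalue"),
    directed = FALSE, vertices = data.frame(name = universe)
  )
  comp <- igraph::components(g)
  ord <- order(-comp$csize, vapply(split(universe, comp$membership), min,
                                   character(1)))
  relabel <- match(seq_along(comp$csize), ord)
  component_id <- sprintf("C%04d", relabel[comp$membership])
  nodes <- tibble::tibble(sequence_id = universe, component_id = component_id)
  if (!is.null(annotations)) {
    nodes$taxon_class <- annotation_lookup(universe, annotations, "taxon_class")
  } else {
    nodes$taxon_class <- NA_character_
  }
  g <- igraph::set_vertex_attr(g, "taxon_class", value = nodes$taxon_class)
  g <- igraph::set_vertex_attr(g, "component_id", value = nodes$component_id)
  structure(list(graph = g, nodes = nodes,
                 n_components = length(unique(component_id))),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d sequences, %d edges, %d connected component(s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$n_components))
  invisible(x)
}

component_subgraphs <- function(network) {
  ids <- sort(unique(network$nodes$component_id))
  lapply(setNames(ids, ids), function(cid) {
    igraph::induced_subgraph(
      network$graph, network$nodes$sequence_id[network$nodes$component_id == cid])
  })
}

#' Per-component topology metrics
#'
#' For every connected component: node and edge counts, the global density
#' (realised over possible connections — the "clustering coefficient" in
#' the loose sense), the average local clustering coefficient
#' (transitivity), the diameter in edge counts, and the number of
#' articulation points (overall and those whose betweenness exceeds the
#' component mean by `z_cut` standard deviations). Single-node components
#' get density and clustering 1 by convention and are flagged `degenerate`.
#'
#' @param network A `gene_network`.
#' @param z_cut Significance rule for "high" betweenness: node betweenness
#'   above component mean + `z_cut` * sd (default 2).
#' @return One row per component.
#' @export
component_metrics <- function(network, z_cut = 2) {
  subs <- component_subgraphs(network)
  purrr::imap_dfr(subs, function(g, cid) {
    n <- igraph::vcount(g)
    m <- igraph::ecount(g)
    if (n == 1) {
      return(tibble::tibble(
        component_id = cid, n_nodes = 1L, n_edges = 0L, density = 1,
        clustering_local = 1, diameter = 0L, n_articulation = 0L,
        n_high_betweenness_articulation = 0L, degenerate = TRUE))
    }
    btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
    art <- igraph::articulation_points(g)
    art_names <- igraph::V(g)$name[art]
    hi <- btw > mean(btw) + z_cut * sd(btw)
    hi[is.na(hi)] <- FALSE
    loc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    tibble::tibble(
      component_id = cid, n_nodes = n, n_edges = m,
      density = igraph::edge_density(g),
      clustering_local = mean(loc),
      diameter = as.integer(igraph::diameter(g, directed = FALSE,
                                             weights = NA)),
      n_articulation = length(art_names),
      n_high_betweenness_articulation =
        sum(igraph::V(g)$name[hi] %in% art_names),
      degenerate = FALSE)
  })
}

#' Per-node centrality metrics
#'
#' Betweenness (sum over node pairs of the fraction of shortest paths
#' through the node), articulation-point status (global, and local within
#' the node's community subgraph), community membership and the
#' high-betweenness flag (component mean + `z_cut` sd).
#'
#' @inheritParams component_metrics
#' @return One row per sequence.
#' @export
node_metrics <- function(network, z_cut = 2) {
  subs <- component_subgraphs(network)
  purrr::imap_dfr(subs, function(g, cid) {
    nm <- igraph::V(g)$name
    btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
    art_names <- igraph::V(g)$name[igraph::articulation_points(g)]
    comm <- community_membership(g)
    local_art <- character(0)
    for (cm in unique(comm)) {
      sub <- igraph::induced_subgraph(g, nm[comm == cm])
      local_art <- c(local_art,
                     igraph::V(sub)$name[igraph::articulation_points(sub)])
    }
    hi <- if (length(nm) > 1) btw > mean(btw) + z_cut * sd(btw) else FALSE
    hi[is.na(hi)] <- FALSE
    tibble::tibble(
      component_id = cid, sequence_id = nm, betweenness = unname(btw),
      articulation = nm %in% art_names,
      local_articulation = nm %in% local_art,
      high_betweenness = unname(hi),
      community = paste0(cid, "_m", comm))
  })
}

# Greedy modularity-maximising agglomeration; deterministic.
community_membership <- function(g) {
  if (igraph::vcount(g) < 2) return(rep(1L, igraph::vcount(g)))
  as.integer(igraph::membership(
    igraph::cluster_fast_greedy(g, weights = NULL)))
}

#' Detect communities within each component
#'
#' Modularity-maximising partition by greedy agglomeration, computed
#' independently per connected component. Deterministic.
#'
#' @param network A `gene_network`.
#' @return Tibble `(component_id, sequence_id, community)`.
#' @export
detect_communities <- function(network) {
  subs <- component_subgraphs(network)
  purrr::imap_dfr(subs, function(g, cid) {
    tibble::tibble(component_id = cid, sequence_id = igraph::V(g)$name,
                   community = paste0(cid, "_m", community_membership(g)))
  })
}

#' Classify components by topological signature
#'
#' Heuristic triage of gene-family components into evolutionary-mode
#' classes: `clique_like` (dense, no articulation points — conserved
#' families such as translation initiation factor I), `bridged` (sparse, or
#' held together by high-betweenness articulation points — tinkered
#' families such as restriction endonuclease S subunits) and
#' `intermediate` (community-structured divergence, e.g. type V secretion
#' proteins). Thresholds are configurable heuristics.
#'
#' @param metrics Output of [component_metrics()].
#' @param density_clique Density at or above which a component with no
#'   articulation point is `clique_like` (default 0.8).
#' @param density_bridged Density at or below which a component is
#'   `bridged` (default 0.3).
#' @return `metrics` with a `topology_class` column.
#' @export
classify_topology <- function(metrics, density_clique = 0.8,
                              density_bridged = 0.3) {
  metrics |>
    dplyr::mutate(topology_class = dplyr::case_when(
      .data$density >= density_clique & .data$n_articulation == 0 ~ "clique_like",
      .data$density <= density_bridged |
        .data$n_high_betweenness_articulation >= 1 ~ "bridged",
      TRUE ~ "intermediate"))
}

#' Export a gene network as GraphML
#'
#' @param network A `gene_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_graphml <- function(network, path) {
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}
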