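# Build a gene network from an explicit edge list.
network_from_edges <- function(from, to, isolated = character(0)) {
  hits <- dplyr::bind_rows(purrr::map2(from, to, hit_row, ident = 90))
  if (length(isolated) > 0) {
    hits <- dplyr::bind_rows(hits, purrr::map(isolated, ~hit_row(.x, .x, 100)))
  }
  build_gene_network(hits)
}

test_that("a 4-clique is classified clique_like", {
  pairs <- utils::combn(paste0("k", 1:4), 2)
  net <- network_from_edges(pairs[1, ], pairs[2, ])
  m <- classify_topology(component_metrics(net))
  expect_equal(nrow(m), 1)
  expect_equal(m$density, 1)
  expect_equal(m$clustering_local, 1)
  expect_equal(m$topology_class, "clique_like")
})

test_that("a moderately dense cycle with no articulation is intermediate", {
  # 5-cycle: density 5/10 = 0.5, 2-connected
  v <- paste0("c", 1:5)
  net <- network_from_edges(v, v[c(2:5, 1)])
  m <- classify_topology(component_metrics(net), density_bridged = 0.3)
  expect_equal(m$density, 0.5)
  expect_equal(m$n_articulation, 0L)
  expect_equal(m$topology_class, "intermediate")
})

test_that("two triangles joined through x yield cut vertices x, a1, b1", {
  net <- network_from_edges(
    c("a1", "a2", "a3", "b1", "b2", "b3", "a1", "b1"),
    c("a2", "a3", "a1", "b2", "b3", "b1", "x", "x"))
  m <- component_metrics(net)
  expect_equal(m$n_articulation, 3L)
  nm <- node_metrics(net)
  expect_setequal(nm$sequence_id[nm$articulation], c("x", "a1", "b1"))
  # x carries every cross-triangle shortest path
  expect_equal(max(nm$betweenness), nm$betweenness[nm$sequence_id == "x"])
})

test_that("sparse chain components are classified bridged", {
  v <- paste0("p", 1:7)  # path graph: density 6/21 < 0.3
  net <- network_from_edges(v[-7], v[-1])
  m <- classify_topology(component_metrics(net))
  expect_lt(m$density, 0.3)
  expect_equal(m$topology_class, "bridged")
})

test_that("components and ids match a union-find oracle", {
  set.seed(99)
  ids <- sprintf("n%02d", 1:15)
  from <- sample(ids, 12, replace = TRUE)
  to <- sample(ids, 12, replace = TRUE)
  keep <- from != to
  net <- network_from_edges(from[keep], to[keep], isolated = ids)
  memb <- oracle_components(ids, from[keep], to[keep])
  pkg <- setNames(net$nodes$component_id, net$nodes$sequence_id)[ids]
  for (i in 1:14) for (j in (i + 1):15) {
    expect_equal(unname(pkg[i] == pkg[j]), unname(memb[i] == memb[j]))
  }
  expect_equal(net$n_components, length(unique(memb)))
})

test_that("betweenness and articulation match brute force on random graphs", {
  set.seed(123)
  for (rep in 1:4) {
    n <- sample(8:15, 1)
    ids <- sprintf("v%02d", seq_len(n))
    adj <- matrix(0L, n, n)
    n_edges <- sample(n:(2 * n), 1)
    for (k in seq_len(n_edges)) {
      ij <- sample(n, 2)
      adj[ij[1], ij[2]] <- adj[ij[2], ij[1]] <- 1L
    }
    ut <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
    if (nrow(ut) == 0) next
    net <- network_from_edges(ids[ut[, 1]], ids[ut[, 2]], isolated = ids)
    nm <- node_metrics(net)
    btw_oracle <- setNames(oracle_betweenness(adj), ids)
    art_oracle <- setNames(oracle_articulation(adj), ids)
    expect_equal(setNames(nm$betweenness, nm$sequence_id)[ids],
                 btw_oracle, tolerance = 1e-9)
    expect_equal(setNames(nm$articulation, nm$sequence_id)[ids],
                 art_oracle)
  }
})

test_that("single-node components use the degenerate convention", {
  net <- network_from_edges("a", "b", isolated = "z")
  m <- component_metrics(net)
  lone <- m[m$n_nodes == 1, ]
  expect_equal(lone$density, 1)
  expect_equal(lone$clustering_local, 1)
  expect_equal(lone$diameter, 0L)
  expect_true(lone$degenerate)
})

test_that("two cliques joined by one edge split into two communities", {
  a <- utils::combn(paste0("a", 1:4), 2)
  b <- utils::combn(paste0("b", 1:4), 2)
  net <- network_from_edges(c(a[1, ], b[1, ], "a1"),
                            c(a[2, ], b[2, ], "b1"))
  comm <- detect_communities(net)
  expect_equal(dplyr::n_distinct(comm$community), 2)
  grp <- split(comm$sequence_id, comm$community)
  expect_true(any(vapply(grp, setequal, logical(1), paste0("a", 1:4))))
})

test_that("build_gene_network applies identity and e-value thresholds", {
  hits <- dplyr::bind_rows(
    hit_row("a", "b", 90, ev = 1e-50),
    hit_row("b", "c", 25, ev = 1e-50),   # identity below 30
    hit_row("c", "d", 90, ev = 1e-5))    # e-value above 1e-20
  net <- build_gene_network(hits)
  expect_equal(igraph::ecount(net$graph), 1)
  expect_equal(net$n_components, 3)
})
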