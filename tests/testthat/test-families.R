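test_that("identity below the floor leaves two singleton families", {
  hits <- dplyr::bind_rows(hit_row("a", "b", 65), hit_row("b", "a", 65))
  fam <- cluster_families(hits, identity_min = 70)
  expect_equal(nrow(fam), 2)
  expect_equal(dplyr::n_distinct(fam$family_id), 2)
})

test_that("single linkage matches a union-find oracle on random hit sets", {
  set.seed(42)
  for (rep in 1:5) {
    ids <- sprintf("s%02d", 1:20)
    n_edges <- sample(5:25, 1)
    from <- sample(ids, n_edges, replace = TRUE)
    to <- sample(ids, n_edges, replace = TRUE)
    keep <- from != to
    from <- from[keep]; to <- to[keep]
    hits <- dplyr::bind_rows(purrr::map2(from, to, hit_row, ident = 90))
    fam <- cluster_families(hits, annotations = strain_annotations(ids, "EC1"))
    memb <- oracle_components(ids, from, to)
    pkg <- setNames(fam$family_id, fam$sequence_id)[ids]
    # same partition: pairs agree on together/apart
    for (i in 1:19) for (j in (i + 1):20) {
      expect_equal(unname(pkg[i] == pkg[j]), unname(memb[i] == memb[j]))
    }
  }
})

test_that("better direction wins for asymmetric hit pairs", {
  hits <- dplyr::bind_rows(
    hit_row("a", "b", 75, ev = 1e-50),   # passes identity_min 70
    hit_row("b", "a", 60, ev = 1e-10))   # fails both thresholds
  fam <- cluster_families(hits, identity_min = 70, evalue_max = 1e-20)
  expect_equal(dplyr::n_distinct(fam$family_id), 1)
})

test_that("true_bbh keeps only reciprocal best hits", {
  ann <- strain_annotations(c("a1", "a2", "b1"), c("EC1", "EC1", "EC2"))
  # a1's best hit in EC2 is b1, but b1's best hit in EC1 is a2.
  hits <- dplyr::bind_rows(
    hit_row("a1", "b1", 90, bits = 300),
    hit_row("b1", "a1", 90, bits = 300),
    hit_row("b1", "a2", 95, bits = 400),
    hit_row("a2", "b1", 95, bits = 400))
  rbh <- reciprocal_best_hits(hits, ann)
  expect_equal(nrow(rbh), 1)
  expect_equal(c(rbh$seq_a, rbh$seq_b), c("a2", "b1"))
  fam_true <- cluster_families(hits, mode = "true_bbh", annotations = ann)
  expect_equal(dplyr::n_distinct(fam_true$family_id), 2)  # {a2,b1}, {a1}
  fam_false <- cluster_families(hits)
  expect_equal(dplyr::n_distinct(fam_false$family_id), 1)
})

test_that("parameter errors are raised before clustering", {
  hits <- hit_row("a", "b", 90)
  expect_error(cluster_families(hits, evalue_max = 0), "evalue_max")
  expect_error(cluster_families(hits, identity_min = 101), "identity_min")
  expect_error(cluster_families(hits, mode = "true_bbh"), "annotations")
})

test_that("annotated sequences without passing hits become singletons", {
  ann <- strain_annotations(c("a", "b", "lonely"), c("EC1", "EC2", "EC3"))
  hits <- dplyr::bind_rows(hit_row("a", "b", 90))
  fam <- cluster_families(hits, annotations = ann)
  expect_setequal(fam$sequence_id, c("a", "b", "lonely"))
  expect_equal(dplyr::n_distinct(fam$family_id), 2)
})

test_that("cluster_families recovers simulated families exactly", {
  sim <- simulate_hits(n_families = 15, seed = 11)
  fam <- cluster_families(sim$hits, annotations = sim$annotations)
  truth <- setNames(sim$truth$family_id, sim$truth$sequence_id)
  pkg <- setNames(fam$family_id, fam$sequence_id)
  ids <- sim$truth$sequence_id
  same_truth <- outer(truth[ids], truth[ids], "==")
  same_pkg <- outer(pkg[ids], pkg[ids], "==")
  expect_true(all(same_truth == same_pkg))
})

test_that("spurious hits above the e-value ceiling do not merge families", {
  sim <- simulate_hits(n_families = 10, n_spurious = 8, seed = 12)
  fam <- cluster_families(sim$hits, annotations = sim$annotations)
  truth <- setNames(sim$truth$family_id, sim$truth$sequence_id)
  pkg <- setNames(fam$family_id, fam$sequence_id)
  ids <- sim$truth$sequence_id
  expect_true(all(outer(truth[ids], truth[ids], "==") ==
                    outer(pkg[ids], pkg[ids], "==")))
})

test_that("family ids are deterministic: size-sorted, ties by smallest member", {
  hits <- dplyr::bind_rows(
    hit_row("z1", "z2", 90), hit_row("z2", "z3", 90),  # size 3
    hit_row("m1", "m2", 90))                            # size 2
  fam <- cluster_families(hits)
  expect_equal(fam$family_id[fam$sequence_id == "z1"], "F00001")
  expect_equal(fam$family_id[fam$sequence_id == "m1"], "F00002")
})

test_that("family_summary counts members per taxon class", {
  ann <- strain_annotations(c("a", "b", "m"), c("EC1", "EC2", "EC1"))
  ann$taxon_class[3] <- "MGE"
  ann$mge_class[3] <- "plasmid"
  hits <- dplyr::bind_rows(hit_row("a", "b", 90), hit_row("b", "m", 90))
  fs <- family_summary(cluster_families(hits), ann)
  expect_equal(nrow(fs), 1)
  expect_equal(fs$n_members, 3L)
  expect_equal(fs$n_MGE, 1L)
})
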