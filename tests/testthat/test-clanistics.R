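test_that("collapse_low_support contracts exactly the weak edges", {
  tr <- ape::read.tree(text = "((A,B)40,C,(D,E)80);")
  out <- collapse_low_support(tr, 50)
  expect_setequal(out$tip.label, tr$tip.label)
  # the 40 edge goes, the 80 edge stays
  expect_equal(out$Nnode, 2)
  kept <- ape::read.tree(text = "((A,B)60,C,(D,E)80);")
  expect_true(ape::all.equal.phylo(collapse_low_support(kept, 50), kept,
                                   use.edge.length = FALSE))
})

test_that("alternating supports on a 6-leaf caterpillar leave one internal edge", {
  tr <- ape::read.tree(text = "((C,((E,F)30,D)90)30,A,B);")
  out <- collapse_low_support(tr, 50)
  n_tip <- ape::Ntip(out)
  expect_equal(sum(out$edge[, 2] > n_tip), 1)
  expect_setequal(out$tip.label, tr$tip.label)
})

test_that("collapse keeps unsupported edges and validates the cutoff", {
  tr <- ape::read.tree(text = "((A,B),C,(D,E)80);")  # first edge: no label
  out <- collapse_low_support(tr, 50)
  expect_equal(out$Nnode, tr$Nnode)
  expect_error(collapse_low_support(tr, 101), "cutoff")
  expect_error(collapse_low_support(tr, -1), "cutoff")
})

test_that("p_score handles the worked examples", {
  tr <- ape::read.tree(text = "((E1,E2),(B1,B2));")
  expect_equal(p_score(tr, c("E1", "E2", "B1", "B2")), 0L)
  expect_equal(p_score(tr, c("E1", "E2")), 1L)
  expect_equal(p_score(tr, character(0)), 0L)
  # alternating caterpillar needs one cut per native
  cat6 <- ape::read.tree(text = "(B1,E1,(B2,(E2,(B3,E3))));")
  expect_equal(p_score(cat6, c("E1", "E2", "E3")), 3L)
})

test_that("e_star closed forms: grouped 0, alternating 1, {2,2} gives 0.5", {
  grouped <- ape::read.tree(text = "(((E1,E2),E3),(B1,B2));")
  expect_equal(e_star(grouped, c("E1", "E2", "E3")), 0)
  alt <- ape::read.tree(text = "(B1,(E1,(E2,B2)));")
  expect_equal(e_star(alt, c("E1", "E2")), 1)
  two_two <- ape::read.tree(
    text = "(((E1,E2),(B1,B2)),((E3,E4),(B3,B4)));")
  expect_equal(e_star(two_two, c("E1", "E2", "E3", "E4")), 0.5)
  expect_true(is.na(e_star(alt, character(0))))
  expect_equal(e_star(alt, "E1"), 0)
})

test_that("classify_clan reproduces the worked classifications", {
  pure <- ape::read.tree(text = "((E1,E2),(E3,E4));")
  expect_equal(classify_clan(pure, pure$tip.label)$classification, "pure")
  clan <- ape::read.tree(text = "((E1,E2),(B1,B2));")
  rep_clan <- classify_clan(clan, c("E1", "E2"))
  expect_equal(rep_clan$classification, "perfect_clan")
  expect_equal(rep_clan$p_score, 1L)
  expect_equal(rep_clan$e_star, 0)
  slice <- ape::read.tree(text = "(B1,(E1,(E2,B2)));")
  rep_slice <- classify_clan(slice, c("E1", "E2"))
  expect_equal(rep_slice$classification, "perfect_slice")
  expect_equal(rep_slice$p_score, 2L)
  expect_false(rep_slice$trivial)
  expect_true(classify_clan(clan, "E1")$trivial)
})

test_that("classification invariants hold on random labelled trees", {
  set.seed(5)
  for (rep in 1:30) {
    n <- sample(4:9, 1)
    tr <- random_unrooted_tree(paste0("L", seq_len(n)))
    natives <- sample(tr$tip.label, sample.int(n, 1))
    rep_row <- classify_clan(tr, natives)
    if (rep_row$classification == "pure") expect_equal(rep_row$p_score, 0L)
    if (rep_row$p_score == 0) expect_equal(rep_row$classification, "pure")
    if (rep_row$classification == "perfect_clan") {
      expect_equal(rep_row$p_score, 1L)
      expect_equal(rep_row$e_star, 0)
    }
    if (rep_row$classification == "perfect_slice") {
      expect_equal(rep_row$p_score, 2L)
    }
  }
})

test_that("native_leaves resolves values through remap", {
  tr <- ape::read.tree(text = "((x1,x2),(y1,z1));")
  ann <- strain_annotations(c("x1", "x2", "y1", "z1"),
                            c("EC1", "EC2", "EC3", "EC4"))
  ann$taxon_class[4] <- "BAC"
  expect_setequal(native_leaves(tr, ann, c("EC1", "EC2")), c("x1", "x2"))
  expect_setequal(
    native_leaves(tr, ann, c("EC1", "EC2"), remap = c(BAC = "EC1")),
    c("x1", "x2", "z1"))
})

test_that("classify_forest + forest_summary aggregate counts and percentages", {
  trees <- list(
    clan = ape::read.tree(text = "((x1,x2),(y1,y2));"),
    pure = ape::read.tree(text = "((x1,x2),(x3,x4));"))
  ann <- strain_annotations(c("x1", "x2", "x3", "x4", "y1", "y2"),
                            c("EC1", "EC2", "EC3", "EC4", "BAC", "BAC"))
  ann$taxon_class[5:6] <- "BAC"
  report <- classify_forest(trees, ann, values = paste0("EC", 1:4))
  expect_equal(report$classification, c("perfect_clan", "pure"))
  s <- forest_summary(report)
  expect_equal(s$n_trees, 2)
  expect_equal(s$counts$n[s$counts$classification == "pure"], 1L)
  expect_equal(sum(s$counts$pct), 100)
  empty <- forest_summary(report[0, ])
  expect_equal(sum(empty$counts$n), 0L)
})

test_that("find_mobile_modules applies all three rules", {
  mk <- function(labels) ape::read.tree(
    text = paste0("(", paste(labels, collapse = ","), ");"))
  ann <- strain_annotations(
    c("p1", "p2", "m1", "m2", "m3", "n1"),
    c("EC1", "EC3", "MGE", "MGE", "MGE", "EC2"))
  ann$taxon_class[3:5] <- "MGE"
  ann$pathogenicity <- c("PATH", "PATH", "OTH", "OTH", "OTH", "NON-PATH")
  forest <- as_gene_forest(
    list(t1 = mk(c("p1", "p2", "m1")),       # MGE+, all PATH, {EC1,EC3}
         t2 = mk(c("p1", "p2", "m2")),       # same profile -> same group
         t3 = mk(c("p1", "p2", "n1", "m3")), # NON-PATH leaf -> excluded
         t4 = mk(c("p1", "p2"))))            # no MGE -> excluded
  mods <- find_mobile_modules(forest, ann)
  expect_equal(sort(unique(mods$tree_id)), c("t1", "t2"))
  expect_equal(dplyr::n_distinct(mods$group_id), 1)
  expect_equal(unique(mods$strain_profile), "EC1,EC3")
})

test_that("planted modules are recovered from a decoy forest", {
  sim <- simulate_forest(
    n_strains = 10, n_trees = 50, core_fraction = 0.3, lgt_rate = 0.5,
    mge_per_event = 0.2, duplicate_rate = 0,
    planted_modules = list(list(n_trees = 2, n_strains = 3),
                           list(n_trees = 2, n_strains = 4),
                           list(n_trees = 3, n_strains = 5)),
    seed = 21)
  mods <- find_mobile_modules(sim$forest, sim$annotations)
  planted <- sim$truth[!is.na(sim$truth$module_id), ]
  # every planted group appears intact in the output
  planted_groups <- split(planted$tree_id, planted$module_id)
  found_groups <- split(mods$tree_id, mods$group_id)
  for (pg in planted_groups) {
    expect_true(any(vapply(found_groups,
                           function(fg) all(pg %in% fg), logical(1))))
  }
  expect_gte(dplyr::n_distinct(mods$group_id), 3)
})
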