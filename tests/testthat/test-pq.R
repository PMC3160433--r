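test_that("induced_quartet_topology follows the support-cutoff rule", {
  tr <- ape::read.tree(text = "((A,B)90,(C,D));")
  q <- induced_quartet_topology(tr, c("A", "B", "C", "D"), 50)
  expect_true(q$resolved)
  expect_equal(canonical_split(q$clans[[1]], q$clans[[2]]),
               canonical_split(c("A", "B"), c("C", "D")))
  expect_false(induced_quartet_topology(tr, c("A", "B", "C", "D"), 95)$resolved)
  star <- ape::read.tree(text = "(A,B,C,D);")
  expect_false(induced_quartet_topology(star, c("A", "B", "C", "D"), 50)$resolved)
  expect_error(induced_quartet_topology(tr, c("A", "B", "C", "Z"), 50),
               "not in tree")
  expect_error(induced_quartet_topology(tr, c("A", "A", "B", "C"), 50),
               "distinct")
})

test_that("unlabelled edges count as supported", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_true(induced_quartet_topology(tr, c("A", "B", "C", "D"), 99)$resolved)
})

test_that("a fully supported 4-strain tree gives frequencies 1 and 0", {
  tr <- ape::read.tree(text = "((s1a,s2a)95,(s3a,s4a)95);")
  ann <- strain_annotations(c("s1a", "s2a", "s3a", "s4a"), paste0("EC", 1:4))
  pqm <- pq_forest(as_gene_forest(tr), ann, n_quartets = 50, seed = 1)
  f <- pqm$frequency
  expect_equal(f["EC1", "EC2"], 1)
  expect_equal(f["EC3", "EC4"], 1)
  expect_equal(f["EC1", "EC3"], 0)
  expect_equal(f["EC2", "EC4"], 0)
  expect_equal(pqm$cooccurrence["EC1", "EC2"], 50L)
})

test_that("sampled frequencies sit within 3 SE of exhaustive enumeration", {
  set.seed(31)
  tr <- random_unrooted_tree(paste0("x", 1:6))
  ann <- strain_annotations(tr$tip.label, paste0("EC", 1:6))
  fs <- as_gene_forest(tr)
  ex <- pq_forest(fs, ann, exhaustive = TRUE)
  sm <- pq_forest(fs, ann, n_quartets = 1000, seed = 32)
  for (i in 1:5) for (j in (i + 1):6) {
    a <- paste0("EC", i); b <- paste0("EC", j)
    p <- ex$frequency[a, b]
    n <- sm$cooccurrence[a, b]
    se <- sqrt(max(p * (1 - p), 0.25 / n) / n)
    expect_lt(abs(sm$frequency[a, b] - p), 3 * se + 1e-12)
  }
})

test_that("pq runs are reproducible under a fixed seed", {
  sim <- simulate_forest(n_strains = 6, n_trees = 5, seed = 8)
  a <- pq_forest(sim$forest, sim$annotations, n_quartets = 100, seed = 99)
  b <- pq_forest(sim$forest, sim$annotations, n_quartets = 100, seed = 99)
  expect_identical(a$cooccurrence, b$cooccurrence)
  expect_identical(a$same_clan, b$same_clan)
})

test_that("trees with fewer than four strains are skipped with a notice", {
  tr <- ape::read.tree(text = "(a,b,(c,d));")
  ann <- strain_annotations(c("a", "b", "c", "d"),
                            c("EC1", "EC2", "EC3", "EC3"))
  expect_message(
    out <- sample_pqs(tr, setNames(ann$taxon_class, ann$sequence_id)),
    "< 4")
  expect_null(out)
})

test_that("pooling sums counts so identical trees double the tallies", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  ann <- strain_annotations(c("a", "b", "c", "d"), paste0("EC", 1:4))
  one <- pq_forest(as_gene_forest(tr), ann, exhaustive = TRUE)
  two <- pq_forest(as_gene_forest(list(tr, tr)), ann, exhaustive = TRUE)
  expect_equal(two$cooccurrence, one$cooccurrence * 2L)
  expect_equal(two$same_clan, one$same_clan * 2L)
  expect_equal(two$frequency, one$frequency)
})

test_that("pq_distance is the one-complement with optional mean imputation", {
  f <- matrix(c(NA, 1, 0, NA,
                1, NA, 0.5, NA,
                0, 0.5, NA, NA,
                NA, NA, NA, NA), 4, byrow = TRUE,
              dimnames = list(paste0("EC", 1:4), paste0("EC", 1:4)))
  pqm <- structure(list(strains = paste0("EC", 1:4),
                        cooccurrence = (!is.na(f)) * 10L,
                        same_clan = round(10 * ifelse(is.na(f), 0, f)),
                        frequency = f, n_trees_sampled = 1L),
                   class = "pq_matrix")
  d <- pq_distance(pqm, impute = "none")
  expect_equal(d$values["EC1", "EC2"], 0)
  expect_equal(d$values["EC1", "EC3"], 1)
  expect_equal(d$values["EC2", "EC3"], 0.5)
  expect_true(d$missing["EC1", "EC4"])
  dm <- pq_distance(pqm, impute = "mean")
  expect_equal(dm$values["EC1", "EC4"], mean(c(0, 1, 0.5)))
  expect_true(dm$missing["EC1", "EC4"])  # imputed pairs stay flagged
})

test_that("partition_forest classifies core, shell and single-copy trees", {
  trees <- list(
    core = ape::read.tree(text = "((a1,b1),(c1,d1));"),
    shell_dup = ape::read.tree(text = "((a1,a2),(b1,c1));"),
    tiny = ape::read.tree(text = "(a1,b1,c1);"))
  ann <- strain_annotations(
    c("a1", "a2", "b1", "c1", "d1"),
    c("EC1", "EC1", "EC2", "EC3", "EC4"))
  p <- partition_forest(as_gene_forest(trees), ann)
  expect_equal(p$core, c(TRUE, FALSE, FALSE))
  expect_equal(p$shell, c(FALSE, TRUE, TRUE))
  expect_equal(p$single_copy, c(TRUE, FALSE, TRUE))
  expect_equal(p$pq_eligible, c(TRUE, FALSE, FALSE))
  expect_true(all(xor(p$core, p$shell)))
})

test_that("planted core/shell splits are recovered exactly", {
  sim <- simulate_forest(n_strains = 8, n_trees = 40, core_fraction = 0.4,
                         duplicate_rate = 0, seed = 14)
  p <- partition_forest(sim$forest, sim$annotations)
  truth <- sim$truth[match(p$tree_id, sim$truth$tree_id), ]
  expect_equal(p$core, truth$core)
  expect_equal(sum(p$core), 16)
})

test_that("mantel_test: design-matrix distances give r = 1, seeds reproduce", {
  taxa <- paste0("EC", 1:8)
  g <- setNames(rep(c("PATH", "NON-PATH"), each = 4), taxa)
  m <- outer(g[taxa], g[taxa], function(a, b) as.numeric(a != b))
  diag(m) <- 0
  dimnames(m) <- list(taxa, taxa)
  mt <- mantel_test(m, g, n_permutations = 99, seed = 3)
  expect_equal(mt$statistic, 1)
  mt2 <- mantel_test(m, g, n_permutations = 99, seed = 3)
  expect_identical(c(mt$statistic, mt$p_value), c(mt2$statistic, mt2$p_value))
  expect_gte(mt$p_value, 1 / 100)
})

test_that("mantel_test validates its inputs", {
  taxa <- paste0("EC", 1:6)
  m <- matrix(0.5, 6, 6, dimnames = list(taxa, taxa)); diag(m) <- 0
  g <- setNames(rep(c("A", "B"), each = 3), taxa)
  expect_error(mantel_test(m, g), "constant")
  m[1, 2] <- m[2, 1] <- 0.9
  expect_error(mantel_test(m, setNames(c("A", rep("B", 5)), taxa)),
               "at least two")
  expect_error(mantel_test(m, g[-1]), "missing")
})

test_that("compare_distance_sets reports a Welch t comparison", {
  set.seed(4)
  taxa <- paste0("EC", 1:10)
  mk <- function(mu) {
    m <- matrix(0, 10, 10, dimnames = list(taxa, taxa))
    m[upper.tri(m)] <- pmin(pmax(rnorm(45, mu, 0.05), 0), 1)
    m + t(m)
  }
  out <- compare_distance_sets(taxon_dist(mk(0.65)), taxon_dist(mk(0.87)))
  expect_s3_class(out, "htest")
  expect_lt(out$estimate[1], out$estimate[2])
  expect_lt(out$statistic, 0)
  expect_lt(out$p.value, 0.01)
})
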