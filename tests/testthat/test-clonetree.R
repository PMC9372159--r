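test_that("CCF computation inverts the expected-VAF relation", {
  # VAF 0.5 at purity 1, CNt 2, multiplicity 1 is a fully clonal mutation
  expect_equal(compute_ccf(15, 30, 1, 2)$ccf, 1)
  # purity and copy-number correction: VAF * (rho*CNt + 2(1-rho)) / (rho*m)
  res <- compute_ccf(10, 40, 0.5, 4, 1)
  expect_equal(res$ccf, 0.25 * (0.5 * 4 + 1) / 0.5)
  flagged <- compute_ccf(30, 30, 0.5, 6, 1)
  expect_true(flagged$flagged)
  expect_equal(flagged$ccf, 1.5)
})

test_that("DP clustering recovers two planted clusters and trivial cases", {
  set.seed(101)
  n <- 200
  alt <- rbind(cbind(rbinom(n, 100, 0.5), rbinom(n, 100, 0.5)),
               cbind(rbinom(n, 100, 0.5), rbinom(n, 100, 0)))
  dep <- matrix(100L, 2 * n, 2, dimnames = list(NULL, c("b1", "b2")))
  colnames(alt) <- c("b1", "b2")
  fit <- cluster_ccf(alt, dep, purity = c(1, 1), iters = 300, burnin = 100,
                     seed = 42)
  fit <- filter_clusters(fit)
  expect_equal(nrow(fit$clusters), 2L)
  truth <- rep(1:2, each = n)
  tab <- table(truth, fit$assignment)
  expect_gte(sum(apply(tab, 1, max)) / sum(!is.na(fit$assignment)), 0.95)
  # recovered CCFs sit near the planted (1,1) and (1,0)
  ccfs <- as.matrix(fit$clusters[, c("ccf_b1", "ccf_b2")])
  expect_equal(unname(sort(round(ccfs[, 2], 1))), c(0, 1), tolerance = 0.1)

  # single planted cluster collapses to one cluster
  one <- cluster_ccf(matrix(rbinom(100, 60, 0.5), 50, 2),
                     matrix(60L, 50, 2), purity = c(1, 1),
                     iters = 150, burnin = 50, seed = 7)
  expect_equal(nrow(filter_clusters(one)$clusters), 1L)

  # no mutations give no clusters
  empty <- cluster_ccf(matrix(0L, 0, 2), matrix(0L, 0, 2), purity = c(1, 1),
                       seed = 1)
  expect_equal(nrow(empty$clusters), 0L)
})

test_that("clustering is deterministic under a seed", {
  set.seed(5)
  alt <- matrix(rbinom(80, 50, 0.4), 40, 2)
  dep <- matrix(50L, 40, 2)
  f1 <- cluster_ccf(alt, dep, purity = c(1, 1), iters = 100, burnin = 20,
                    seed = 99)
  f2 <- cluster_ccf(alt, dep, purity = c(1, 1), iters = 100, burnin = 20,
                    seed = 99)
  expect_identical(f1$assignment, f2$assignment)
  expect_identical(f1$clusters, f2$clusters)
})

test_that("well-separated clusters are counted correctly across seeded runs", {
  set.seed(77)
  hits <- 0L
  runs <- 20L
  for (r in seq_len(runs)) {
    n <- 100
    alt <- rbind(cbind(rbinom(n, 60, 0.5), rbinom(n, 60, 0.5)),
                 cbind(rbinom(n, 60, 0.5), rbinom(n, 60, 0.15)))
    dep <- matrix(60L, 2 * n, 2)
    fit <- filter_clusters(cluster_ccf(alt, dep, purity = c(1, 1),
                                       iters = 150, burnin = 50,
                                       seed = 7000 + r))
    if (nrow(fit$clusters) == 2L) hits <- hits + 1L
  }
  expect_gte(hits / runs, 0.9)
})

test_that("cluster filters apply the count and fraction rules", {
  fit <- make_clusters(c(9800, 19, 25, 150),
                       cbind(b1 = c(1, 0.5, 0.4, 0.3),
                             b2 = c(1, 0.5, 0.4, 0.3)))
  filtered <- filter_clusters(fit)
  # 19 fails the <20 rule; 25 fails the <1% rule (25 < 100); 150 survives
  expect_equal(filtered$clusters$cluster, c(1L, 4L))
  expect_equal(attr(filtered, "removed"), c(2L, 3L))
})

test_that("tree assembly follows the pigeonhole ordering on a toy matrix", {
  fit <- make_clusters(c(1000, 300, 200),
                       cbind(b1 = c(1, 0.6, 0), b2 = c(1, 0, 0.5)))
  tree <- build_tree(fit)
  expect_equal(tree$trunk, 1L)
  expect_equal(tree$clusters$parent, c(NA, 1L, 1L))

  single <- build_tree(make_clusters(500, cbind(b1 = 1, b2 = 1)))
  expect_equal(trunk_proportion(single), 1.0)

  # presence is strict: CCF exactly 0.1 does not count as present
  border <- make_clusters(c(1000, 100),
                          cbind(b1 = c(1, 0.1), b2 = c(1, 0.5)))
  tree_b <- build_tree(border)
  gs <- genetic_similarity(tree_b, c(b1 = "A", b2 = "B"))
  expect_equal(gs$scores["b1", "b2"], 1000 / mean(c(1000, 1100)))

  # no cluster spanning all biopsies yields a flagged forest
  forest <- build_tree(make_clusters(c(100, 100),
                                     cbind(b1 = c(1, 0), b2 = c(0, 1))))
  expect_true(is.na(forest$trunk))
  expect_match(attr(forest, "diagnostic"), "forest")
  expect_error(trunk_proportion(forest), "forest")
})

test_that("GCNIS-shared clusters are folded into the trunk", {
  fit <- make_clusters(c(1000, 200, 150),
                       cbind(gcnis = c(1, 0.8, 0),
                             inv1 = c(1, 0.5, 0.4),
                             inv2 = c(1, 0.5, 0)))
  tree <- build_tree(fit, gcnis_biopsies = "gcnis")
  # cluster 2 spans GCNIS and invasive tissue: merged into the trunk
  expect_equal(nrow(tree$clusters), 2L)
  expect_equal(tree$clusters$n_subs[tree$clusters$cluster == 1L], 1200)
})

test_that("trunk proportion matches hand evaluations with double counting", {
  flat <- make_clusters(c(80, 10, 30), cbind(b1 = c(1, 0.5, 0),
                                             b2 = c(1, 0, 0.5)))
  expect_equal(trunk_proportion(build_tree(flat)), 0.80)

  # shared internal branch of 20 then private tips 10 and 30:
  # tip distances 30 and 50, mean 40 -> 80 / 120
  nested <- make_clusters(c(80, 20, 10, 30),
                          cbind(b1 = c(1, 0.9, 0.5, 0),
                                b2 = c(1, 0.9, 0, 0.5)))
  tree <- build_tree(nested)
  expect_equal(tree$clusters$parent, c(NA, 1L, 2L, 2L))
  expect_equal(trunk_proportion(tree), 80 / 120)
})

test_that("trunk proportion moves the right way when branches grow", {
  base <- make_clusters(c(80, 10, 30), cbind(b1 = c(1, 0.5, 0),
                                             b2 = c(1, 0, 0.5)))
  p0 <- trunk_proportion(build_tree(base))
  tip_grown <- make_clusters(c(80, 10, 60), cbind(b1 = c(1, 0.5, 0),
                                                  b2 = c(1, 0, 0.5)))
  expect_lt(trunk_proportion(build_tree(tip_grown)), p0)
  trunk_grown <- make_clusters(c(120, 10, 30), cbind(b1 = c(1, 0.5, 0),
                                                     b2 = c(1, 0, 0.5)))
  expect_gt(trunk_proportion(build_tree(trunk_grown)), p0)
  expect_true(p0 > 0 && p0 <= 1)
})

test_that("newick export encodes topology and branch lengths", {
  nested <- make_clusters(c(80, 20, 10, 30),
                          cbind(b1 = c(1, 0.9, 0.5, 0),
                                b2 = c(1, 0.9, 0, 0.5)))
  nk <- tree_newick(build_tree(nested))
  expect_match(nk, "^\\(\\(c3:10,c4:30\\)c2:20\\)c1:80;$")
})
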