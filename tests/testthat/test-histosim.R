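test_that("genetic similarity matches the shared-burden hand evaluation", {
  # trunk of 1,000 shared, private clusters of 200 and 600
  fit <- make_clusters(c(1000, 200, 600),
                       cbind(b1 = c(1, 0.8, 0), b2 = c(1, 0, 0.8)))
  gs <- genetic_similarity(fit, c(b1 = "A", b2 = "B"))
  expect_equal(gs$scores["b1", "b2"], 1000 / mean(c(1200, 1600)))
  expect_equal(gs$scores, t(gs$scores))

  # identical presence patterns and burdens give 1
  same <- make_clusters(c(500, 100), cbind(b1 = c(1, 0.5), b2 = c(1, 0.5)))
  expect_equal(genetic_similarity(same, c(b1 = "A", b2 = "B"))$scores["b1", "b2"], 1)

  # a biopsy with no present clusters yields NA scores and a warning
  expect_warning(
    empty <- genetic_similarity(
      make_clusters(c(500, 100), cbind(b1 = c(1, 0.5), b2 = c(0.05, 0.02))),
      c(b1 = "A", b2 = "B")),
    "no present clusters")
  expect_true(is.na(empty$scores["b1", "b2"]))
})

test_that("disjoint cluster presence gives zero genetic similarity", {
  fit <- make_clusters(c(300, 300, 50),
                       cbind(b1 = c(1, 0, 0.05), b2 = c(0, 1, 0.05)))
  gs <- genetic_similarity(fit, c(b1 = "A", b2 = "B"))
  expect_equal(gs$scores["b1", "b2"], 0)
})

test_that("transcriptomic similarity is a correlation over retained genes", {
  co <- small_cohort(seed = 21)
  ts <- transcriptomic_similarity(co$expression)
  expect_equal(unname(diag(ts$scores)), rep(1, nrow(ts$scores)))
  expect_true(all(abs(ts$scores) <= 1 + 1e-12))
  # library-size rescaling leaves TPM, hence the correlation, unchanged
  ex <- co$expression
  ex2 <- expression_study(cbind(ex$counts[, 1, drop = FALSE] * 3L,
                                ex$counts[, -1]),
                          ex$genes, ex$samples)
  colnames(ex2$counts) <- colnames(ex$counts)
  ts2 <- transcriptomic_similarity(ex2)
  expect_equal(ts2$scores, ts$scores, tolerance = 1e-12)
})

test_that("planted histology programs raise intra- over inter-histology similarity", {
  wins <- 0L
  for (s in 1:10) {
    co <- simulate_cohort(cohort_config(n_patients = 1, mutation_rate = 50,
                                        n_genes = 1000, seed = 300 + s))
    ts <- transcriptomic_similarity(co$expression)
    pr <- ts$histology[rownames(ts$scores)]
    up <- which(upper.tri(ts$scores), arr.ind = TRUE)
    intra <- pr[up[, 1]] == pr[up[, 2]]
    if (sum(intra) > 0 && sum(!intra) > 0 &&
        median(ts$scores[up][intra]) > median(ts$scores[up][!intra])) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 8L)
})

test_that("label swapping enumerates exhaustively for small designs", {
  # 4 biopsies, 2 per histology: 6 pairs of which 2 intra -> 15 assignments
  hist <- setNames(c("A", "A", "B", "B"), paste0("b", 1:4))
  sim <- make_similarity(runif(6), 4, hist)
  res <- label_swap_test(sim, n_perm = 1000, seed = 1)
  expect_equal(res$mode, "exhaustive")
  expect_equal(res$n_assignments, 15)
  expect_equal(res$n_intra, 2)

  # perfectly separated scores reach the minimum attainable p
  scores <- matrix(0, 4, 4, dimnames = list(names(hist), names(hist)))
  scores["b1", "b2"] <- scores["b2", "b1"] <- 1
  scores["b3", "b4"] <- scores["b4", "b3"] <- 1
  diag(scores) <- 1
  best <- label_swap_test(similarity_matrix(scores, hist), seed = 1)
  expect_equal(best$p, 1 / 15)

  expect_error(label_swap_test(make_similarity(runif(6), 4,
                                               setNames(rep("A", 4),
                                                        paste0("b", 1:4)))),
               "intra")
})

test_that("sampled-mode p-values use the add-one convention and large designs", {
  set.seed(31)
  hist <- setNames(rep(c("A", "B"), each = 5), paste0("b", 1:10))
  n_pairs <- choose(10, 2)
  sc <- runif(n_pairs)
  sim <- make_similarity(sc, 10, hist)
  res <- label_swap_test(sim, n_perm = 200, seed = 2)
  expect_equal(res$mode, "sampled")
  expect_gte(res$p, 1 / 201)
  expect_lte(res$p, 1)
  # strictly monotone transforms of the scores leave p unchanged
  sim_t <- make_similarity(exp(3 * sc), 10, hist)
  res_t <- label_swap_test(sim_t, n_perm = 200, seed = 2)
  expect_equal(res_t$p, res$p)
})

test_that("exhaustive and sampled label-swap modes agree in distribution", {
  # 5 pairs, 2 intra: 10 assignments; compare the exhaustive null set with
  # a large random sample of swaps on the same scores
  scores <- c(0.9, 0.8, 0.2, 0.4, 0.6)
  n_intra <- 2
  combos <- combn(5, n_intra)
  ex_stats <- apply(combos, 2, function(ix)
    median(scores[ix]) - median(scores[-ix]))
  set.seed(8)
  sm_stats <- replicate(4000, {
    ix <- sample(5, n_intra)
    median(scores[ix]) - median(scores[-ix])
  })
  ks <- suppressWarnings(ks.test(sm_stats, ex_stats))
  expect_gt(ks$p.value, 0.01)
})

test_that("the chromothripsis variance test behaves at its extremes", {
  pool <- c(seq(0.4, 0.9, length.out = 30))
  flat <- chromothripsis_variance_test(rep(0.7, 6), pool, seed = 1)
  expect_equal(flat$p, 1.0)
  # the most extreme pool values give a near-minimal p
  extreme <- chromothripsis_variance_test(c(0.4, 0.42, 0.44, 0.86, 0.88, 0.9),
                                          pool, n_iter = 500, seed = 2)
  expect_lt(extreme$p, 0.02)
  expect_error(chromothripsis_variance_test(rep(0.5, 6), runif(3)), "pool")
  # tiny pools switch to exhaustive enumeration
  small <- chromothripsis_variance_test(c(0.5, 0.6), c(0.4, 0.5, 0.6, 0.7),
                                        n_iter = 1000, seed = 3)
  expect_equal(small$mode, "exhaustive")
})

test_that("the variance test p is uniform when the focal set is null", {
  set.seed(41)
  pv <- replicate(200, {
    pool <- rnorm(40, 0.7, 0.1)
    focal <- sample(pool, 6)
    chromothripsis_variance_test(focal, pool, n_iter = 200,
                                 seed = sample.int(1e6, 1))$p
  })
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
})
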