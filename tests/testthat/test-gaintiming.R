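test_that("multiplicity assignment picks the likelier expected VAF", {
  # pure tetraploid: v1 = 0.25, v2 = 0.5
  expect_equal(assign_multiplicity(15, 30, 1, 4), 2L)
  expect_equal(assign_multiplicity(7, 30, 1, 4), 1L)
  # 2+0 at VAF 1 can only be on both copies
  expect_equal(assign_multiplicity(30, 30, 1, 2), 2L)
  expect_true(is.na(assign_multiplicity(0, 0, 1, 4)))
})

test_that("posterior multiplicity weights average to the planted fraction", {
  set.seed(61)
  n <- 2000; w_true <- 0.1
  m <- ifelse(runif(n) < w_true, 2, 1)
  alt <- rbinom(n, 30, expected_vaf(m, 1, 4))
  mp <- multiplicity_posterior(alt, rep(30, n), 1, 4)
  expect_equal(mp$n2 / n, mean(m == 2), tolerance = 0.25)
  expect_equal(mp$n1 + mp$n2, n)
})

test_that("segment timing inverts the planted accumulation model", {
  # 2+2 with no multiplicity-2 evidence: gain at time 0
  expect_equal(segment_time(40, 0, "2+2", seed = 1)$t, 0)
  # planted t = 0.5 on 2+2: n2 = 2tk, n1 = 4(1-t)k
  st <- segment_time(40, 20, "2+2", seed = 1)
  expect_equal(st$t, 0.5)
  expect_true(st$ci[1] <= 0.5 && st$ci[2] >= 0.5)
  # 2+1 formula: 3 n2 / (2 n2 + n1)
  expect_equal(segment_time(10, 10, "2+1", seed = 1)$t, 1.0)
  expect_error(segment_time(10, 10, "3+2"), "state")
  expect_error(segment_time(0, 0, "2+2"), "counts")
})

test_that("segment timing is invariant to count scaling", {
  for (k in c(0.5, 2, 10)) {
    expect_equal(segment_time(40 * k, 20 * k, "2+2", seed = 2)$t,
                 segment_time(40, 20, "2+2", seed = 2)$t)
    expect_equal(segment_time(30 * k, 5 * k, "2+1", seed = 2)$t,
                 segment_time(30, 5, "2+1", seed = 2)$t)
  }
})

test_that("wide bootstrap intervals mark segments ineligible", {
  lo <- segment_time(3, 1, "2+2", seed = 3)
  expect_false(lo$eligible)
  hi <- segment_time(400, 200, "2+2", seed = 3)
  expect_true(hi$eligible)
})

test_that("the copy-number-adjusted burden follows the printed formula", {
  timed <- data.frame(state = c("2+1", "2+2"), n1 = c(20, 25), n2 = c(10, 5),
                      start = c(1, 1), end = c(50e6, 50e6),
                      eligible = TRUE)
  est <- pre_dup_burden(timed, genome_length = 100e6)
  # pre = 15; totals on 2+1/2+0 = 30; totals on all = 60
  expect_equal(est$num_pre_dup_subs, 15)
  expect_equal(est$cn_adjusted_burden, 15 + 15 * 30 / 60)
  expect_equal(est$genome_wide_burden, est$cn_adjusted_burden * 100e6 / 100e6)

  # pure 2+2 leaves the adjustment term at zero
  all22 <- data.frame(state = "2+2", n1 = 30, n2 = 10, start = 1, end = 1e6,
                      eligible = TRUE)
  expect_equal(pre_dup_burden(all22, 1e6)$cn_adjusted_burden, 10)

  # covering half the genome doubles the extrapolated burden
  half <- pre_dup_burden(all22, 2e6)
  expect_equal(half$genome_wide_burden, 20)

  expect_error(pre_dup_burden(data.frame(state = "2+2", n1 = 1, n2 = 1,
                                         start = 1, end = 10,
                                         eligible = FALSE)), "eligible")
})

test_that("the adjusted burden is invariant to segment subdivision", {
  whole <- data.frame(state = c("2+1", "2+2"), n1 = c(20, 24), n2 = c(10, 6),
                      start = c(1, 1), end = c(40e6, 40e6), eligible = TRUE)
  split <- data.frame(state = c("2+1", "2+1", "2+2", "2+2"),
                      n1 = c(12, 8, 14, 10), n2 = c(4, 6, 2, 4),
                      start = c(1, 20e6 + 1, 1, 20e6 + 1),
                      end = c(20e6, 40e6, 20e6, 40e6), eligible = TRUE)
  a <- pre_dup_burden(whole, 80e6)
  b <- pre_dup_burden(split, 80e6)
  expect_equal(a$cn_adjusted_burden, b$cn_adjusted_burden)
  expect_equal(a$genome_wide_burden, b$genome_wide_burden)
})

test_that("WGD classification applies the weighted ploidy rule", {
  expect_true(classify_wgd(sample_profile(1, 2.9, 30, 0)))   # boundary in
  expect_false(classify_wgd(sample_profile(1, 2.0, 30, 0.4)))
  expect_true(classify_wgd(sample_profile(1, 4.0, 30, 0)))
  # monotone in ploidy and homozygosity separately
  ps <- seq(1.5, 4.5, by = 0.1)
  calls_p <- vapply(ps, function(p)
    classify_wgd(sample_profile(1, p, 30, 0.2)), logical(1))
  expect_true(all(diff(calls_p) >= 0))
  hs <- seq(0, 1, by = 0.05)
  calls_h <- vapply(hs, function(h)
    classify_wgd(sample_profile(1, 2.3, 30, h)), logical(1))
  expect_true(all(diff(calls_h) >= 0))
})

test_that("burden-to-division conversion doubles the haploid rate", {
  d <- cell_divisions(5.8)
  expect_equal(d$point, 5.8 / 1.2)
  expect_equal(d$divisions, 5)
  expect_equal(cell_divisions(0)$divisions, 0)
  expect_equal(cell_divisions(12)$range, c(12 / 1.4, 12 / 1.0))
  expect_error(cell_divisions(5, rate_per_haploid = c(0, 0.7)), "positive")
})

test_that("the asymptotic age regression recovers generating parameters", {
  ages <- 0:60
  fit <- fit_age_curve(ages, -0.59 + 574.02 * exp(-0.26 * ages))
  expect_equal(round(fit$a, 2), -0.59)
  expect_equal(round(fit$b, 2), 574.02)
  expect_equal(round(fit$c, 2), -0.26)

  fit2 <- fit_age_curve(seq(0, 40, by = 2), 10 + 100 * exp(-0.5 * seq(0, 40, by = 2)))
  expect_equal(round(fit2$a, 2), 10)
  expect_equal(round(fit2$b, 2), 100)

  flat <- fit_age_curve(c(1, 5, 9, 20), rep(3, 4))
  expect_true(flat$degenerate)
  expect_equal(flat$a, 3)
  expect_equal(flat$b, 0)
  expect_error(fit_age_curve(c(1, 1, 2), c(1, 2, 3)), "distinct ages")
})

test_that("focal event heuristics apply the size and copy thresholds", {
  segs <- data.frame(chrom = c("12", "12", "4", "8"),
                     start = c(1, 1, 1, 1),
                     end = c(5e5, 2e6, 3e5, 5e5),
                     total_cn = c(10, 12, 0, 4))
  genes <- data.frame(gene = c("KRAS", "ONC2"), chrom = c("12", "4"),
                      start = c(1e5, 1e5), end = c(2e5, 2e5))
  res <- classify_focal_events(segs, average_ploidy = 3.5, genes = genes)
  expect_equal(res$call[res$chrom == "12" & res$end == 5e5], "amplification")
  expect_equal(res$call[res$end == 2e6], "gain")       # 1-10 Mb tier
  expect_equal(res$call[res$chrom == "4"], "deletion")
  expect_false("8" %in% res$chrom)                     # CN 4 is unremarkable
  expect_equal(res$genes[res$chrom == "4"], "ONC2")
  # below ploidy 2.7 the amplification threshold drops to 5 copies
  low <- classify_focal_events(data.frame(chrom = "1", start = 1, end = 9e5,
                                          total_cn = 6), 2.2)
  expect_equal(low$call, "amplification")
})
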