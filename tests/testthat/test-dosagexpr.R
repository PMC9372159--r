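test_that("library QC counts expressed features with strict boundaries", {
  counts <- cbind(low = c(rep(5L, 999), rep(0L, 501)),
                  edge = c(rep(5L, 1000), rep(0L, 500)),
                  high = rep(10L, 1500))
  kept <- qc_libraries(counts)
  expect_equal(kept, c("edge", "high"))  # 999 removed, exactly 1000 kept
  expect_equal(qc_libraries(matrix(0L, 0, 0)), character(0))
})

test_that("TPM normalises length-rates to one million per library", {
  one <- matrix(50L, 1, 1, dimnames = list("g1", "s1"))
  expect_equal(as.vector(tpm(one, 1000)), 1e6)
  two <- matrix(c(10L, 10L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  res <- tpm(two, c(1000, 2000))
  expect_equal(as.vector(res), c(2e6 / 3, 1e6 / 3))
  set.seed(51)
  m <- matrix(rpois(600, 20), 100, 6)
  expect_equal(unname(colSums(tpm(m, rpois(100, 1500) + 200))),
               rep(1e6, 6), tolerance = 1e-9)
  expect_warning(tpm(matrix(0L, 2, 1), c(100, 100)), "zero total")
})

test_that("differential expression recovers planted fold changes", {
  set.seed(52)
  # balanced up/down effects in a small gene fraction keep the TPM
  # composition stable so fold-changes read on the planted scale
  n_genes <- 2000
  lens <- rep(1000L, n_genes)
  base <- rlnorm(n_genes, log(50), 0.4)
  planted <- 1:20
  planted_dn <- 21:40
  mu_a <- base
  mu_a[planted] <- mu_a[planted] * 4
  mu_a[planted_dn] <- mu_a[planted_dn] / 4
  counts <- cbind(
    sapply(1:10, function(i) rpois(n_genes, mu_a)),
    sapply(1:10, function(i) rpois(n_genes, base)))
  dimnames(counts) <- list(paste0("g", 1:n_genes),
                           c(paste0("a", 1:10), paste0("b", 1:10)))
  genes <- data.frame(gene = rownames(counts), chrom = "1",
                      start = seq_len(n_genes) * 1000,
                      end = seq_len(n_genes) * 1000 + 999,
                      cytoband = "1p1", biotype = "protein_coding",
                      exclusion_set = "", length = lens)
  samples <- data.frame(sample = colnames(counts),
                        histology = rep("h", 20), tumour = "t",
                        is_normal_tubule = rep(c(FALSE, TRUE), each = 10))
  ex <- expression_study(counts, genes, samples)
  de <- differential_expression(ex, paste0("a", 1:10), paste0("b", 1:10))
  expect_equal(median(de$log2fc[planted]), 2, tolerance = 0.15)
  expect_equal(median(de$log2fc[planted_dn]), -2, tolerance = 0.15)
  expect_gte(mean(de$p_adj[planted] < 0.01), 0.9)
  # false positives among null genes controlled at BH 0.05
  expect_lte(mean(de$p_adj[-c(planted, planted_dn)] < 0.05, na.rm = TRUE),
             0.05)
  # identical groups give exactly zero fold change
  de0 <- differential_expression(ex, paste0("a", 1:5), paste0("a", 1:5))
  expect_equal(de0$log2fc, rep(0, n_genes))
  expect_true(all(de$p_adj >= de$p, na.rm = TRUE))
})

test_that("histology blocking cancels opposite per-histology effects", {
  set.seed(53)
  n_genes <- 200
  base <- rep(100, n_genes)
  up <- base * 2; dn <- base / 2
  counts <- cbind(
    sapply(1:4, function(i) rpois(n_genes, up)),
    sapply(1:4, function(i) rpois(n_genes, dn)),
    sapply(1:8, function(i) rpois(n_genes, base)))
  dimnames(counts) <- list(paste0("g", 1:n_genes),
                           c(paste0("h1_", 1:4), paste0("h2_", 1:4),
                             paste0("n", 1:8)))
  genes <- data.frame(gene = rownames(counts), chrom = "1",
                      start = 1:n_genes, end = 1:n_genes + 10,
                      cytoband = "1p1", biotype = "protein_coding",
                      exclusion_set = "", length = 1000L)
  samples <- data.frame(sample = colnames(counts), histology = "x",
                        tumour = "t", is_normal_tubule = FALSE)
  ex <- expression_study(counts, genes, samples)
  blocking <- setNames(c(rep("h1", 4), rep("h2", 4), rep("n", 8)),
                       colnames(counts))
  de <- differential_expression(ex, colnames(counts)[1:8],
                                colnames(counts)[9:16],
                                blocking = blocking)
  expect_lt(max(abs(de$log2fc)), 0.25)
})

test_that("rolling fold-change tracks average 50 consecutive genes", {
  n <- 200
  de <- data.frame(gene = paste0("g", 1:n), chrom = "12",
                   start = seq_len(n) * 1e4,
                   log2fc = rep(1, n))
  tr <- rolling_logfc(de, "12")
  expect_equal(nrow(tr), n - 49)
  expect_equal(unique(tr$mean_log2fc), 1)
  # a step from 0 to 2 ramps linearly over the window
  de$log2fc <- c(rep(0, 100), rep(2, 100))
  tr2 <- rolling_logfc(de, "12")
  expect_equal(tr2$mean_log2fc[1], 0)
  expect_equal(tr2$mean_log2fc[nrow(tr2)], 2)
  ramp <- tr2$mean_log2fc[tr2$mean_log2fc > 0 & tr2$mean_log2fc < 2]
  expect_equal(length(ramp), 49)
  expect_equal(diff(ramp), rep(2 / 50, 48))
  # fewer genes than the window yields an empty track with a message
  expect_message(empty <- rolling_logfc(de[1:49, ], "12"), "fewer")
  expect_equal(nrow(empty), 0)
})

test_that("cytoband enrichment flags planted bands and skips small ones", {
  set.seed(54)
  n <- 400
  de <- data.frame(gene = paste0("g", 1:n),
                   log2fc = rnorm(n),
                   cytoband = rep(c("12p1", "1q1", "2q1", "tiny"),
                                  c(30, 180, 186, 4)))
  de$log2fc[de$cytoband == "12p1"] <- de$log2fc[de$cytoband == "12p1"] + 2
  res <- cytoband_enrichment(de)
  row <- res[res$cytoband == "12p1", ]
  expect_lt(row$p_adj, 0.01)
  expect_equal(row$direction, "+")
  expect_true("tiny" %in% attr(res, "skipped"))
  # permuted assignments give roughly uniform p-values
  de$cytoband <- sample(de$cytoband)
  res_null <- cytoband_enrichment(de)
  expect_gt(min(res_null$p_adj), 0.01)
})

test_that("dosage permutation detects planted arm effects and rejects bad input", {
  set.seed(55)
  n <- 600
  de <- data.frame(gene = paste0("g", 1:n), log2fc = rnorm(n))
  target <- paste0("g", 1:50)
  de$log2fc[1:50] <- de$log2fc[1:50] + 1
  pool <- paste0("g", 51:600)
  res <- dosage_permutation(de, target, pool, n_draws = 2000, seed = 9)
  expect_equal(res$p, 1 / 2001)
  expect_equal(res$n_target, 50)
  # adding a constant to every fold change leaves p unchanged
  de2 <- de; de2$log2fc <- de2$log2fc + 5
  res2 <- dosage_permutation(de2, target, pool, n_draws = 2000, seed = 9)
  expect_equal(res2$p, res$p)
  expect_error(dosage_permutation(de, target, pool[1:10], n_draws = 10),
               "smaller")
  expect_error(dosage_permutation(de, target, pool, n_draws = 0), "n_draws")
})

test_that("near-baseline gene pools follow segment copy number", {
  genes <- data.frame(gene = c("a", "b", "c"), chrom = c("1", "1", "2"),
                      start = c(100, 5000, 100))
  segs <- data.frame(chrom = c("1", "1", "2"), start = c(1, 4000, 1),
                     end = c(3999, 10000, 1000), total_cn = c(4, 6, 3.8))
  expect_equal(genes_near_baseline(genes, segs, ploidy = 4), c("a", "c"))
})

test_that("the simulated 12p dosage effect is detected and the null is quiet", {
  run_dosage <- function(mult, seed) {
    co <- simulate_cohort(cohort_config(n_patients = 2, mutation_rate = 20,
                                        n_genes = 1600,
                                        dosage_multiplier = mult,
                                        seed = seed))
    ex <- co$expression
    kept <- qc_libraries(ex$counts)
    tum <- intersect(kept, ex$samples$sample[!ex$samples$is_normal_tubule])
    nrm <- intersect(kept, ex$samples$sample[ex$samples$is_normal_tubule])
    de <- differential_expression(ex, tum, nrm,
                                  blocking = setNames(ex$samples$histology,
                                                      ex$samples$sample))
    target <- ex$genes$gene[ex$genes$arm == "12p"]
    seg <- subset(co$segments, sample == "P1_b1")
    seg$total_cn <- seg$major + seg$minor
    pool <- genes_near_baseline(ex$genes, seg,
                                co$profiles[["P1_b1"]]$ploidy)
    dosage_permutation(de, target, pool, n_draws = 2000, seed = seed)$p
  }
  p_gain <- vapply(1:5, function(s) run_dosage(2, 700 + s), numeric(1))
  expect_gte(mean(p_gain < 1e-3), 0.8)
})
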