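# Expression QC, TPM normalisation, a self-contained differential
# expression routine against normal seminiferous tubules, 50-gene rolling
# fold-change tracks, cytoband enrichment, and the chromosome-arm (12p)
# dosage permutation test.

#' Construct an expression study
#'
#' @param counts genes x biopsies integer matrix with dimnames.
#' @param genes data.frame with `gene`, `chrom`, `start`, `end`,
#'   `cytoband`, `biotype`, `exclusion_set`, `length` (bases), rows aligned
#'   with `counts`.
#' @param samples data.frame with `sample`, `histology`, `tumour`,
#'   `is_normal_tubule`, rows aligned with `counts` columns.
#' @return an object of class `expression_study` with a lazily computed
#'   `tpm` slot.
#' @export
expression_study <- function(counts, genes, samples) {
  stopifnot(is.matrix(counts), nrow(genes) == nrow(counts),
            nrow(samples) == ncol(counts),
            all(c("gene", "length") %in% names(genes)),
            all(genes$length > 0))
  structure(list(counts = counts, genes = genes, samples = samples,
                 tpm = tpm(counts, genes$length)),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d genes x %d libraries (%d normal tubule)\n",
              nrow(x$counts), ncol(x$counts), sum(x$samples$is_normal_tubule)))
  invisible(x)
}

#' Filter failed or low-quality libraries
#'
#' A gene counts as expressed in a library when at least
#' `expressed_min_reads` reads map to it; libraries expressing fewer than
#' `min_features` genes (strictly fewer) are removed.
#'
#' @param counts genes x libraries count matrix.
#' @param expressed_min_reads reads for a gene to count as expressed;
#'   default 5.
#' @param min_features minimum expressed genes per library; default 1000.
#' @return character vector of retained library names (column indices when
#'   unnamed).
#' @export
qc_libraries <- function(counts, expressed_min_reads = 5, min_features = 1000) {
  stopifnot(is.matrix(counts))
  if (ncol(counts) == 0L) return(character(0))
  n_expressed <- colSums(counts >= expressed_min_reads)
  keep <- n_expressed >= min_features
  if (is.null(colnames(counts))) which(keep) else colnames(counts)[keep]
}

#' Transcripts per million
#'
#' Per-library length-normalised rates scaled to sum to 1e6. Libraries
#' whose total rate is zero yield an all-`NA` column with a warning.
#'
#' @param counts genes x libraries matrix.
#' @param lengths gene lengths in bases.
#' @return TPM matrix of the same shape.
#' @export
tpm <- function(counts, lengths) {
  stopifnot(nrow(counts) == length(lengths), all(lengths > 0))
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) {
    warning("library(ies) with zero total rate: ",
            paste(colnames(counts)[tot == 0], collapse = ", "))
  }
  out <- sweep(rate, 2L, tot, "/") * 1e6
  out[, tot == 0] <- NA_real_
  out
}

# Vectorised per-gene Welch two-sample test on log2(TPM + 1).
.row_welch <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se2 == 0] <- ifelse(ma[se2 == 0] == mb[se2 == 0], 1, 0)
  p
}

#' Differential expression between library groups
#'
#' A deliberately self-contained location-test routine (the package's
#' bespoke content is the downstream permutation and rolling machinery; an
#' externally computed table with the same columns can be supplied to those
#' functions instead). Log2 fold-change is
#' log2((mean TPM_a + 1) / (mean TPM_b + 1)); p-values come from a
#' two-sided unequal-variance (Welch) test on log2(TPM + 1), adjusted by
#' Benjamini-Hochberg across genes. With a histology `blocking` factor the
#' fold-change is the unweighted mean of per-histology fold-changes and the
#' test is run on within-histology-centred values.
#'
#' @param expr an [expression_study()].
#' @param group_a,group_b character vectors of library names.
#' @param blocking optional named histology vector (names = libraries).
#' @return data.frame of class `de_result`: `gene`, `log2fc`, `p`, `p_adj`
#'   plus the gene annotation columns. Groups of size < 2 yield `NA`
#'   p-values but fold-changes are still reported.
#' @export
differential_expression <- function(expr, group_a, group_b, blocking = NULL) {
  stopifnot(inherits(expr, "expression_study"))
  tpm_m <- expr$tpm
  miss <- setdiff(c(group_a, group_b), colnames(tpm_m))
  if (length(miss)) stop("unknown libraries: ", paste(miss, collapse = ", "))
  la <- log2(tpm_m[, group_a, drop = FALSE] + 1)
  lb <- log2(tpm_m[, group_b, drop = FALSE] + 1)
  if (is.null(blocking)) {
    lfc <- log2(rowMeans(tpm_m[, group_a, drop = FALSE]) + 1) -
      log2(rowMeans(tpm_m[, group_b, drop = FALSE]) + 1)
  } else {
    blocks <- unique(blocking[group_a])
    per_block <- vapply(blocks, function(h) {
      ga <- group_a[blocking[group_a] == h]
      log2(rowMeans(tpm_m[, ga, drop = FALSE]) + 1) -
        log2(rowMeans(tpm_m[, group_b, drop = FALSE]) + 1)
    }, numeric(nrow(tpm_m)))
    lfc <- rowMeans(matrix(per_block, nrow = nrow(tpm_m)))
    centre <- function(m, grp) {
      for (h in unique(grp)) {
        cols <- which(grp == h)
        m[, cols] <- m[, cols, drop = FALSE] -
          rowMeans(m[, cols, drop = FALSE])
      }
      m
    }
    la <- centre(la, blocking[group_a]) + rowMeans(la)
  }
  p <- if (length(group_a) >= 2 && length(group_b) >= 2) {
    .row_welch(la, lb)
  } else rep(NA_real_, nrow(tpm_m))
  out <- data.frame(gene = expr$genes$gene, log2fc = lfc, p = p,
                    p_adj = stats::p.adjust(p, method = "BH"))
  out <- cbind(out, expr$genes[, setdiff(names(expr$genes), "gene"),
                               drop = FALSE])
  class(out) <- c("de_result", "data.frame")
  rownames(out) <- NULL
  out
}

#' Rolling average log2 fold-change along a chromosome
#'
#' Centred moving average of the log2 fold-change over `window` consecutive
#' genes ordered by start coordinate (gene rank, not base pairs, is the
#' support); each window is anchored at the median position of its genes.
#'
#' @param de a `de_result`.
#' @param chrom chromosome to profile.
#' @param window genes per window; default 50.
#' @return data.frame with `chrom`, `centre_pos`, `mean_log2fc`
#'   (`n_genes - window + 1` rows; empty with a message when fewer than
#'   `window` genes are available).
#' @export
rolling_logfc <- function(de, chrom, window = 50) {
  d <- de[de$chrom == chrom & !is.na(de$log2fc), , drop = FALSE]
  d <- d[order(d$start), , drop = FALSE]
  n <- nrow(d)
  if (n < window) {
    message(sprintf("chromosome %s has %d genes, fewer than the %d-gene window",
                    chrom, n, window))
    return(data.frame(chrom = character(0), centre_pos = numeric(0),
                      mean_log2fc = numeric(0)))
  }
  cs <- c(0, cumsum(d$log2fc))
  idx <- seq_len(n - window + 1L)
  means <- (cs[idx + window] - cs[idx]) / window
  centre <- vapply(idx, function(i)
    stats::median(d$start[i:(i + window - 1L)]), numeric(1))
  data.frame(chrom = chrom, centre_pos = centre, mean_log2fc = means)
}

#' Cytoband-level enrichment of expression changes
#'
#' Two-sided rank-sum comparison of each band's log2 fold-changes against
#' all other genes, Benjamini-Hochberg adjusted across bands; bands with
#' fewer than `min_genes` genes are skipped and listed.
#'
#' @param de a `de_result` with a `cytoband` column.
#' @param min_genes minimum genes per tested band; default 5.
#' @return data.frame with `cytoband`, `n_genes`, `direction` ("+"/"-"),
#'   `p`, `p_adj`; skipped bands in attribute `skipped`.
#' @export
cytoband_enrichment <- function(de, min_genes = 5) {
  stopifnot("cytoband" %in% names(de))
  d <- de[!is.na(de$log2fc), , drop = FALSE]
  tab <- table(d$cytoband)
  test_bands <- names(tab)[tab >= min_genes]
  skipped <- setdiff(names(tab), test_bands)
  res <- lapply(test_bands, function(b) {
    x <- d$log2fc[d$cytoband == b]
    y <- d$log2fc[d$cytoband != b]
    wt <- stats::wilcox.test(x, y, exact = FALSE)
    data.frame(cytoband = b, n_genes = length(x),
               direction = if (stats::median(x) >= stats::median(y)) "+" else "-",
               p = wt$p.value)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  attr(out, "skipped") <- skipped
  out
}

#' Genes on segments near baseline ploidy
#'
#' Assigns genes to copy-number segments by their start coordinate and
#' returns those whose segment total copy number lies within
#' `near_baseline` of the sample's ploidy estimate.
#'
#' @param genes data.frame with `gene`, `chrom`, `start`.
#' @param segments data.frame with `chrom`, `start`, `end`, `total_cn`
#'   (1-based inclusive).
#' @param ploidy baseline ploidy estimate.
#' @param near_baseline allowed absolute deviation; default 0.5.
#' @return character vector of gene names.
#' @export
genes_near_baseline <- function(genes, segments, ploidy, near_baseline = 0.5) {
  cn <- rep(NA_real_, nrow(genes))
  for (i in seq_len(nrow(segments))) {
    hit <- genes$chrom == segments$chrom[i] &
      genes$start >= segments$start[i] & genes$start <= segments$end[i]
    cn[hit] <- segments$total_cn[i]
  }
  genes$gene[!is.na(cn) & abs(cn - ploidy) <= near_baseline]
}

#' Dosage permutation test for a target gene set
#'
#' Tests whether the mean log2 fold-change over the target genes (e.g. the
#' genes on a gained chromosome arm retained in the differential expression
#' table) exceeds what random gene sets of the same size drawn from
#' near-baseline-ploidy regions achieve:
#' p = (1 + #\{null means >= observed\}) / (n_draws + 1), one-sided.
#' Draws are without replacement within each draw (set
#' `replace = TRUE` for with-replacement sensitivity analysis). Genes
#' missing from `de` (filtered for low expression) are excluded from both
#' the target and the pool.
#'
#' @param de a `de_result`.
#' @param target_genes character vector of target gene names.
#' @param pool_genes character vector of near-baseline genes (e.g. from
#'   [genes_near_baseline()]).
#' @param n_draws random samples; default 100000.
#' @param replace draw genes with replacement within a draw; default FALSE.
#' @param seed integer seed.
#' @return list with `p`, `observed`, `n_target`, `n_pool`, `null_mean`.
#' @export
dosage_permutation <- function(de, target_genes, pool_genes,
                               n_draws = 100000, replace = FALSE,
                               seed = NULL) {
  if (n_draws < 1) stop("'n_draws' must be >= 1")
  lfc <- de$log2fc[match(target_genes, de$gene)]
  lfc <- lfc[!is.na(lfc)]
  # The pool is used as supplied: on real data a gained target arm is never
  # near baseline ploidy, and removing target genes from a pool that
  # legitimately contains them breaks exchangeability under the null.
  pool <- de$log2fc[match(pool_genes, de$gene)]
  pool <- pool[!is.na(pool)]
  k <- length(lfc)
  if (k == 0L) stop("no target genes retained in the DE table")
  if (!replace && length(pool) < k) {
    stop(sprintf("near-baseline pool (%d genes) smaller than target set (%d)",
                 length(pool), k))
  }
  observed <- mean(lfc)
  with_seed(seed, {
    null_means <- vapply(seq_len(n_draws), function(i)
      mean(pool[sample.int(length(pool), k, replace = replace)]), numeric(1))
    list(p = (1 + sum(null_means >= observed)) / (n_draws + 1),
         observed = observed, n_target = k, n_pool = length(pool),
         null_mean = mean(null_means))
  })
}
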