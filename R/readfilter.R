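# Post-caller variant filtering and QC for multi-region microbiopsy
# sequencing: hard filters with reason codes, multi-sample pileup rescue,
# a panel-based beta-binomial site error test with Benjamini-Hochberg
# correction, and callable-length-adjusted mutation burden.

#' Construct a per-sample copy-number profile
#'
#' Bundles the quantities that drive sample eligibility and whole-genome
#' duplication classification: purity (tumour cell fraction), weighted
#' average ploidy, mean sequencing coverage, and the length-weighted
#' fraction of the genome with a homozygous (minor allele 0) state, each
#' weighted by subclonality where subclonal segments exist.
#'
#' @param purity tumour purity in (0, 1].
#' @param ploidy subclonality-weighted average ploidy, > 0.
#' @param coverage mean tumour sequencing coverage, >= 0.
#' @param homozygous_fraction subclonality-weighted homozygous genome
#'   fraction in [0, 1].
#' @return an object of class `sample_profile`.
#' @export
sample_profile <- function(purity, ploidy, coverage = 0, homozygous_fraction = 0) {
  assert_prob(purity, "purity", open_left = TRUE)
  if (!is.finite(ploidy) || ploidy <= 0) stop("'ploidy' must be > 0")
  if (!is.finite(coverage) || coverage < 0) stop("'coverage' must be >= 0")
  assert_prob(homozygous_fraction, "homozygous_fraction")
  structure(list(purity = purity, ploidy = ploidy, coverage = coverage,
                 homozygous_fraction = homozygous_fraction),
            class = "sample_profile")
}

#' @export
print.sample_profile <- function(x, ...) {
  cat(sprintf(
    "sample_profile: purity %.3f, ploidy %.3f, coverage %.1fx, hom. fraction %.3f\n",
    x$purity, x$ploidy, x$coverage, x$homozygous_fraction))
  invisible(x)
}

#' Average reads per chromosome copy
#'
#' The expected number of reads supporting each copy of a chromosome in a
#' tumour sample of given purity, ploidy and mean coverage:
#' purity / (purity * ploidy + (1 - purity) * 2) * coverage.
#' Samples need >= 5 reads per copy for clustering and >= 7 for copy-number
#' gain timing.
#'
#' @param profile a [sample_profile()].
#' @return reads per chromosome copy (numeric scalar).
#' @export
reads_per_copy <- function(profile) {
  stopifnot(inherits(profile, "sample_profile"))
  with(profile, purity / ((purity * ploidy) + ((1 - purity) * 2)) * coverage)
}

# Reason codes for hard filtering, applied conjunctively. Row order of the
# input never matters: each rule is evaluated independently.
.hard_filter_codes <- c(
  ALIGN_SCORE   = "median alignment score < 140 (substitutions)",
  CLIPPED       = "half or more supporting reads clipped",
  MIN_SUPPORT   = "bulk substitutions need >= 4 alt reads and >= 10x coverage",
  INDEL_QUAL    = "indel quality score < 300",
  INDEL_SUPPORT = "indels need >= 5 alt reads (and >= 10x coverage in bulk)",
  GERMLINE_VAF  = "VAF >= 0.2 in matched normal or unmatched panel",
  AMBIG_READS   = "unknown/ambiguous reads exceed alt reads",
  LOW_MAPQ      = "half or more reads at locus have mapping quality < 20"
)

#' Apply hard variant filters with reason codes
#'
#' Conjunctive post-caller filters for substitutions and indels in either
#' laser-capture microdissection or bulk mode. Boundary conventions:
#' clipping and low-mapping-quality rules fail at exactly one half;
#' ambiguous reads fail only when strictly greater than alt reads;
#' germline VAF fails at >= 0.2.
#'
#' @param summaries data.frame with columns `alt`, `total`, and, as needed
#'   for the declared class/mode: `median_align_score`, `clipped_fraction`,
#'   `lowmapq_reads`, `ambiguous_reads`, `normal_vaf`, `panel_vaf`,
#'   `quality` (indels).
#' @param variant_class `"substitution"` or `"indel"`.
#' @param mode `"microdissection"` or `"bulk"`.
#' @return `summaries` with logical `pass` and character `reasons`
#'   (comma-separated failure codes, `""` when passing).
#' @export
apply_hard_filters <- function(summaries,
                               variant_class = c("substitution", "indel"),
                               mode = c("microdissection", "bulk")) {
  variant_class <- match.arg(variant_class)
  mode <- match.arg(mode)
  stopifnot(is.data.frame(summaries))
  need <- c("alt", "total")
  need <- c(need, if (variant_class == "substitution") "median_align_score"
            else "quality")
  missing_cols <- setdiff(need, names(summaries))
  if (length(missing_cols)) {
    stop("missing column(s) required for ", variant_class, "/", mode, ": ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(summaries)
  col <- function(nm, default = NA_real_) {
    if (nm %in% names(summaries)) summaries[[nm]] else rep(default, n)
  }
  fail <- list()
  if (variant_class == "substitution") {
    fail$ALIGN_SCORE <- col("median_align_score") < 140
    if (mode == "bulk") {
      fail$MIN_SUPPORT <- summaries$alt < 4 | summaries$total < 10
    }
  } else {
    fail$INDEL_QUAL <- col("quality") < 300
    fail$INDEL_SUPPORT <- summaries$alt < 5 |
      (mode == "bulk" & summaries$total < 10)
  }
  fail$CLIPPED <- col("clipped_fraction", 0) >= 0.5
  fail$GERMLINE_VAF <- col("normal_vaf", 0) >= 0.2 | col("panel_vaf", 0) >= 0.2
  fail$AMBIG_READS <- col("ambiguous_reads", 0) > summaries$alt
  fail$LOW_MAPQ <- ifelse(summaries$total > 0,
                          col("lowmapq_reads", 0) / summaries$total >= 0.5, FALSE)
  fail <- lapply(fail, function(f) !is.na(f) & f)
  fmat <- do.call(cbind, fail)
  summaries$pass <- rowSums(fmat) == 0L
  summaries$reasons <- apply(fmat, 1L, function(r)
    paste(names(fail)[r], collapse = ","))
  summaries
}

#' Multi-sample pileup rescue of low-depth variants
#'
#' Given per-site, per-sample counts from a pileup of every substitution
#' called across a patient's samples (reads already restricted to base
#' quality >= 25 and mapping quality >= 30 upstream), removes sites whose
#' mean coverage across the patient's samples is <= `mean_cov_max_fail`
#' (probable mapping artefacts) and forwards the rest to the panel error
#' test.
#'
#' @param alt sites x samples matrix of alt read counts.
#' @param depth sites x samples matrix of total read counts.
#' @param mean_cov_max_fail sites with mean coverage <= this are dropped
#'   (inclusive boundary); default 10.
#' @return integer vector of retained site row indices (named if `alt` has
#'   rownames).
#' @export
pileup_rescue <- function(alt, depth, mean_cov_max_fail = 10) {
  stopifnot(is.matrix(depth), all(dim(alt) == dim(depth)))
  if (nrow(depth) == 0L) return(integer(0))
  keep <- which(rowMeans(depth) > mean_cov_max_fail)
  if (!is.null(rownames(alt))) names(keep) <- rownames(alt)[keep]
  keep
}

#' Fit the panel-based beta-binomial site error model
#'
#' Estimates a locus-specific sequencing error rate from an unmatched panel
#' of normal samples prepared on the same platform. Per-site mean error is
#' the pseudocount-regularised pooled alt fraction; a single global
#' overdispersion is fitted by the method of moments across all sites
#' (per-site overdispersion fits are unstable at panel depths).
#'
#' @param panel a `panel_counts` object (see [simulate_panel()]) or a list
#'   with matrices `alt` and `depth` (sites x samples).
#' @param pseudocounts two positive numbers added to pooled alt and ref
#'   totals; default c(0.5, 0.5).
#' @return an object of class `panel_error_model` with fields `mu`
#'   (per-site mean error), `rho` (global overdispersion), `pseudocounts`,
#'   and `untestable` (sites with zero panel depth).
#' @export
fit_panel_error <- function(panel, pseudocounts = c(0.5, 0.5)) {
  stopifnot(all(pseudocounts > 0), length(pseudocounts) == 2L)
  alt <- panel$alt; depth <- panel$depth
  stopifnot(is.matrix(alt), all(dim(alt) == dim(depth)))
  if (ncol(alt) < 2L) stop("panel must contain >= 2 samples")
  tot_alt <- rowSums(alt)
  tot_depth <- rowSums(depth)
  untestable <- tot_depth == 0
  mu <- (tot_alt + pseudocounts[1L]) / (tot_depth + sum(pseudocounts))
  mu <- pmin(mu, 0.499)
  # Method-of-moments overdispersion pooled over (site, sample) cells:
  # Var(alt/n | mu) = mu (1-mu) (1 + rho (n-1)) / n.
  use <- depth > 0 & !untestable[row(depth)]
  p_hat <- ifelse(depth > 0, alt / pmax(depth, 1L), NA_real_)
  mu_mat <- matrix(mu, nrow = nrow(alt), ncol = ncol(alt))
  e2 <- (p_hat - mu_mat)^2
  v0 <- mu_mat * (1 - mu_mat) / depth              # binomial part
  vslope <- mu_mat * (1 - mu_mat) * (depth - 1) / depth
  num <- sum(e2[use] - v0[use])
  den <- sum(vslope[use])
  rho <- if (den > 0) num / den else 0
  rho <- min(max(rho, 1e-6), 0.5)
  structure(list(mu = mu, rho = rho, pseudocounts = pseudocounts,
                 untestable = untestable),
            class = "panel_error_model")
}

#' @export
print.panel_error_model <- function(x, ...) {
  cat(sprintf(
    "panel_error_model: %d sites, median error %.2e, overdispersion %.3g\n",
    length(x$mu), stats::median(x$mu), x$rho))
  invisible(x)
}

#' Beta-binomial rescue of low-depth variants
#'
#' For each (site, sample) pair, computes the one-sided upper-tail
#' beta-binomial probability of observing at least the seen alt count under
#' the panel error model, applies Benjamini-Hochberg correction, and calls
#' a variant present where the adjusted p-value is below `alpha`.
#'
#' @param alt sites x samples matrix of alt counts (rows aligned with the
#'   model's sites).
#' @param depth sites x samples matrix of total counts.
#' @param model a `panel_error_model` from [fit_panel_error()].
#' @param alpha adjusted p-value threshold; default 0.001.
#' @param pool `"sites_samples"` (default) corrects across every test in
#'   the patient; `"sites"` corrects within each sample separately.
#' @return list with matrices `p`, `p_adj` and logical `present`.
#' @export
betabinom_rescue <- function(alt, depth, model, alpha = 0.001,
                             pool = c("sites_samples", "sites")) {
  pool <- match.arg(pool)
  stopifnot(inherits(model, "panel_error_model"),
            is.matrix(alt), all(dim(alt) == dim(depth)),
            nrow(alt) == length(model$mu))
  if (any(alt > depth)) stop("alt counts exceed total counts")
  p <- matrix(
    pbetabinom_upper(as.vector(alt), as.vector(depth),
                     rep(model$mu, times = ncol(alt)), model$rho),
    nrow = nrow(alt), dimnames = dimnames(alt))
  p[depth == 0] <- 1
  p_adj <- if (pool == "sites_samples") {
    matrix(stats::p.adjust(as.vector(p), method = "BH"),
           nrow = nrow(p), dimnames = dimnames(p))
  } else {
    apply(p, 2L, stats::p.adjust, method = "BH")
  }
  list(p = p, p_adj = p_adj, present = p_adj < alpha)
}

#' Mutation burden per callable megabase
#'
#' The callable genome length is the number of bases covered by >= 4 reads
#' minus the bases masked by the variant callers; the burden is the
#' mutation count divided by the callable length in Mb.
#'
#' @param n_mutations number of mutations (substitutions or indels).
#' @param depth_track data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `depth`.
#' @param masked_regions optional data.frame with `chrom`, `start`, `end`
#'   (0-based half-open) to subtract.
#' @param min_depth minimum callable depth; default 4.
#' @return list with `callable_bases` and `burden_per_mb` (`NA` when the
#'   callable length is zero).
#' @export
mutation_burden <- function(n_mutations, depth_track, masked_regions = NULL,
                            min_depth = 4) {
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(depth_track)))
  callable <- 0
  for (chr in unique(depth_track$chrom)) {
    d <- depth_track[depth_track$chrom == chr & depth_track$depth >= min_depth, ]
    x <- cbind(d$start, d$end)
    m <- if (!is.null(masked_regions)) {
      mm <- masked_regions[masked_regions$chrom == chr, ]
      cbind(mm$start, mm$end)
    } else matrix(numeric(0), ncol = 2L)
    callable <- callable + interval_uncovered(x, m)
  }
  if (callable <= 0) {
    return(list(callable_bases = 0, burden_per_mb = NA_real_))
  }
  list(callable_bases = callable,
       burden_per_mb = n_mutations / (callable / 1e6))
}
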