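# Timing clonal copy-number gains in mutation time from mutation
# multiplicity, the copy-number-adjusted pre-duplication burden, WGD
# classification, conversion of burdens into primordial germ cell (PGC)
# divisions, the asymptotic burden-vs-age regression, and focal
# amplification/deletion heuristics.
#
# Mutation time runs over [0, 1] along the accumulation of clonal
# substitutions. On a duplicated allele, mutations acquired before the gain
# sit on both derivative copies (multiplicity 2) while later mutations sit
# on one copy (multiplicity 1), so the multiplicity-2 fraction of a
# segment's mutations dates the gain. Timeable states are 2+0, 2+1 and 2+2
# (major+minor copies).

.timed_states <- c("2+0", "2+1", "2+2")

#' Expected variant allele fraction at a given multiplicity
#'
#' VAF = m * purity / (purity * CNt + 2 * (1 - purity)), capped at 1.
#' @param m multiplicity (copies carrying the mutation).
#' @param purity tumour purity.
#' @param cnt local total copy number.
#' @return expected VAF.
#' @export
expected_vaf <- function(m, purity, cnt) {
  pmin(m * purity / (purity * cnt + 2 * (1 - purity)), 1)
}

#' Maximum-likelihood mutation multiplicity
#'
#' Assigns each clonal mutation the multiplicity (1 or 2) whose expected
#' VAF has the higher binomial likelihood for the observed read counts.
#' Ties go to multiplicity 1. Zero-depth mutations are unassigned (`NA`).
#'
#' @param alt,total alt and total read counts (vectorised).
#' @param purity tumour purity.
#' @param cnt local total copy number (vectorised).
#' @return integer vector of multiplicities in {1, 2}, `NA` where total = 0.
#' @export
assign_multiplicity <- function(alt, total, purity, cnt) {
  n <- max(length(alt), length(total), length(cnt))
  alt <- rep_len(alt, n); total <- rep_len(total, n); cnt <- rep_len(cnt, n)
  v1 <- expected_vaf(1, purity, cnt)
  v2 <- expected_vaf(2, purity, cnt)
  ll1 <- stats::dbinom(alt, total, v1, log = TRUE)
  ll2 <- stats::dbinom(alt, total, v2, log = TRUE)
  out <- ifelse(ll2 > ll1, 2L, 1L)
  out[total == 0] <- NA_integer_
  out
}

#' Posterior multiplicity weights with mixture prior estimated per segment
#'
#' Rather than hard-assigning each mutation, fits the segment's
#' multiplicity-2 mixture weight by maximum likelihood over the binomial
#' mixture of the two expected VAFs, and returns per-mutation posterior
#' probabilities of multiplicity 2. Summing these gives an (approximately
#' unbiased) soft multiplicity-2 count that behaves much better than hard
#' counts when the true multiplicity-2 fraction is small, as it is for
#' early whole-genome duplication.
#'
#' @inheritParams assign_multiplicity
#' @return list with `w2` (fitted mixture weight), `posterior` (per-mutation
#'   probability of multiplicity 2), `n2` and `n1` (soft counts).
#' @export
multiplicity_posterior <- function(alt, total, purity, cnt) {
  n <- max(length(alt), length(total), length(cnt))
  alt <- rep_len(alt, n); total <- rep_len(total, n); cnt <- rep_len(cnt, n)
  keep <- total > 0
  v1 <- expected_vaf(1, purity, cnt)
  v2 <- expected_vaf(2, purity, cnt)
  l1 <- stats::dbinom(alt, total, v1)
  l2 <- stats::dbinom(alt, total, v2)
  nll <- function(w) -sum(log(w * l2[keep] + (1 - w) * l1[keep] + 1e-300))
  opt <- stats::optimize(nll, c(0, 1), tol = 1e-8)
  w2 <- opt$minimum
  post <- rep(NA_real_, n)
  post[keep] <- w2 * l2[keep] / (w2 * l2[keep] + (1 - w2) * l1[keep] + 1e-300)
  list(w2 = w2, posterior = post,
       n2 = sum(post[keep]), n1 = sum(1 - post[keep]))
}

#' Time a copy-number gain from multiplicity counts
#'
#' Converts the multiplicity-1 and multiplicity-2 mutation counts of a
#' segment into the mutation time of its gain:
#' t = 2 n2 / (2 n2 + n1) for 2+0 and 2+2 states, and
#' t = 3 n2 / (2 n2 + n1) for 2+1, truncated to [0, 1].
#' The 95% confidence interval is the percentile interval over multinomial
#' bootstrap resamples of the counts; segments with a CI width >= 0.5 are
#' flagged ineligible (low confidence).
#'
#' Counts may be fractional (e.g. posterior-weighted counts from
#' [multiplicity_posterior()]).
#'
#' @param n1,n2 multiplicity-1 and multiplicity-2 mutation counts.
#' @param state copy-number state, one of "2+0", "2+1", "2+2".
#' @param n_boot bootstrap resamples; default 200.
#' @param conf confidence level; default 0.95.
#' @param seed optional integer seed for the bootstrap.
#' @return list with `t`, `ci` (lo, hi), `eligible`, `state`, `n1`, `n2`.
#' @export
segment_time <- function(n1, n2, state, n_boot = 200, conf = 0.95, seed = NULL) {
  state <- as.character(state)
  if (!state %in% .timed_states) {
    stop("state must be one of ", paste(.timed_states, collapse = ", "),
         "; got ", state)
  }
  if (n1 < 0 || n2 < 0 || n1 + n2 <= 0) stop("need n1 + n2 >= 1 non-negative counts")
  t_of <- function(n1, n2) {
    num <- if (state == "2+1") 3 * n2 else 2 * n2
    min(max(num / (2 * n2 + n1), 0), 1)
  }
  t_hat <- t_of(n1, n2)
  n_tot <- n1 + n2
  ci <- with_seed(seed, {
    draws <- stats::rbinom(n_boot, size = max(1L, round(n_tot)),
                           prob = n2 / n_tot)
    scale <- n_tot / max(1L, round(n_tot))
    ts <- vapply(draws, function(k)
      t_of((max(1L, round(n_tot)) - k) * scale, k * scale), numeric(1))
    stats::quantile(ts, probs = c((1 - conf) / 2, 1 - (1 - conf) / 2),
                    names = FALSE)
  })
  list(t = t_hat, ci = ci, eligible = (ci[2] - ci[1]) < 0.5,
       state = state, n1 = n1, n2 = n2)
}

#' Time all segments of a sample
#'
#' Applies multiplicity assignment and [segment_time()] across a segment
#' table, using only mutations falling on timeable (2+0, 2+1, 2+2)
#' segments.
#'
#' @param segments data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive), `major`, `minor`.
#' @param mutations data.frame with `chrom`, `pos`, `alt`, `total`.
#' @param purity tumour purity.
#' @param method `"posterior"` (default) uses soft posterior counts from
#'   [multiplicity_posterior()]; `"hard"` uses maximum-likelihood
#'   assignments.
#' @param n_boot,seed passed to [segment_time()].
#' @return `segments` with added columns `state`, `n1`, `n2`, `t`, `ci_lo`,
#'   `ci_hi`, `eligible` (`NA` for untimeable states or empty segments).
#' @export
time_segments <- function(segments, mutations, purity,
                          method = c("posterior", "hard"),
                          n_boot = 200, seed = NULL) {
  method <- match.arg(method)
  stopifnot(all(c("chrom", "start", "end", "major", "minor") %in% names(segments)),
            all(c("chrom", "pos", "alt", "total") %in% names(mutations)))
  segments$state <- paste0(segments$major, "+", segments$minor)
  segments$n1 <- segments$n2 <- NA_real_
  segments$t <- segments$ci_lo <- segments$ci_hi <- NA_real_
  segments$eligible <- FALSE
  for (i in seq_len(nrow(segments))) {
    if (!segments$state[i] %in% .timed_states) next
    sel <- mutations$chrom == segments$chrom[i] &
      mutations$pos >= segments$start[i] & mutations$pos <= segments$end[i] &
      mutations$total > 0
    if (!any(sel)) next
    cnt <- segments$major[i] + segments$minor[i]
    if (method == "posterior") {
      mp <- multiplicity_posterior(mutations$alt[sel], mutations$total[sel],
                                   purity, cnt)
      n1 <- mp$n1; n2 <- mp$n2
    } else {
      m <- assign_multiplicity(mutations$alt[sel], mutations$total[sel],
                               purity, cnt)
      n1 <- sum(m == 1L, na.rm = TRUE); n2 <- sum(m == 2L, na.rm = TRUE)
    }
    if (n1 + n2 <= 0) next
    st <- segment_time(n1, n2, segments$state[i], n_boot = n_boot,
                       seed = if (is.null(seed)) NULL else seed + i)
    segments$n1[i] <- n1; segments$n2[i] <- n2
    segments$t[i] <- st$t
    segments$ci_lo[i] <- st$ci[1]; segments$ci_hi[i] <- st$ci[2]
    segments$eligible[i] <- st$eligible
  }
  segments
}

#' Copy-number-adjusted pre-duplication burden
#'
#' Sums the multiplicity-2 (pre-duplication) mutation counts across
#' eligible timed segments and adjusts for the copy-number configuration:
#' pre-duplication mutations on the minor allele of 2+0 and 2+1 segments
#' are invisible (the allele was lost or never duplicated), so the raw
#' count is inflated by the fraction of all eligible-segment substitutions
#' lying on 2+1/2+0 segments:
#'
#'   adjusted = pre + pre * (total subs on 2+1, 2+0) / (total subs on all)
#'
#' The adjusted burden is then extrapolated genome-wide by the ratio of the
#' genome length to the bases covered by eligible segments.
#'
#' @param timed a segment table from [time_segments()] (columns `state`,
#'   `n1`, `n2`, `eligible`, `start`, `end`).
#' @param genome_length total genome length for extrapolation; default the
#'   GRCh37 autosomal length 2,875,001,522.
#' @return an object of class `timing_estimate`: `num_pre_dup_subs`,
#'   `num_total_subs_21_20`, `num_total_subs_all`, `cn_adjusted_burden`,
#'   `covered_bases`, `genome_wide_burden`.
#' @export
pre_dup_burden <- function(timed, genome_length = 2875001522) {
  el <- timed$eligible %in% TRUE & timed$state %in% .timed_states
  if (!any(el)) {
    stop("no eligible timed segments; pre-duplication burden undefined")
  }
  t_el <- timed[el, ]
  pre <- sum(t_el$n2)
  tot_all <- sum(t_el$n1 + t_el$n2)
  tot_2120 <- sum((t_el$n1 + t_el$n2)[t_el$state %in% c("2+1", "2+0")])
  adjusted <- pre + pre * (tot_2120 / tot_all)
  covered <- sum(t_el$end - t_el$start + 1)
  structure(list(
    num_pre_dup_subs = pre,
    num_total_subs_21_20 = tot_2120,
    num_total_subs_all = tot_all,
    cn_adjusted_burden = adjusted,
    covered_bases = covered,
    genome_wide_burden = adjusted * genome_length / covered
  ), class = "timing_estimate")
}

#' @export
print.timing_estimate <- function(x, ...) {
  cat(sprintf(
    paste0("timing_estimate: %.1f raw pre-duplication subs, ",
           "%.1f CN-adjusted, %.1f genome-wide (%.0f Mb covered)\n"),
    x$num_pre_dup_subs, x$cn_adjusted_burden, x$genome_wide_burden,
    x$covered_bases / 1e6))
  invisible(x)
}

#' Classify whole-genome duplication
#'
#' A sample is called whole-genome duplicated when its
#' subclonality-weighted ploidy is at least 2.9 minus twice its
#' subclonality-weighted homozygous genome fraction (boundary inclusive).
#'
#' @param profile a [sample_profile()].
#' @return logical.
#' @export
classify_wgd <- function(profile) {
  stopifnot(inherits(profile, "sample_profile"))
  profile$ploidy >= 2.9 - 2 * profile$homozygous_fraction
}

#' Convert a pre-duplication burden to PGC cell divisions
#'
#' Divides the genome-wide pre-duplication substitution burden by twice the
#' published 0.5-0.7 substitutions per haploid genome per primordial germ
#' cell division (doubled to a per-diploid-genome rate). The point estimate
#' uses the 0.6 midpoint and is rounded to the nearest integer.
#'
#' @param burden genome-wide pre-duplication substitution burden, >= 0.
#' @param rate_per_haploid lower and upper per-haploid-division rates;
#'   default c(0.5, 0.7).
#' @return list with `point` (unrounded), `divisions` (rounded point) and
#'   `range` (divisions at the upper and lower rate).
#' @export
cell_divisions <- function(burden, rate_per_haploid = c(0.5, 0.7)) {
  if (any(rate_per_haploid <= 0)) stop("rates must be positive")
  if (burden < 0) stop("burden must be >= 0")
  mid <- mean(rate_per_haploid)
  point <- burden / (2 * mid)
  list(point = point, divisions = round(point),
       range = c(burden / (2 * max(rate_per_haploid)),
                 burden / (2 * min(rate_per_haploid))))
}

#' Fit the asymptotic burden-vs-age regression
#'
#' Least-squares fit of y = a + b * exp(c * age), profiling over the rate
#' constant c: for fixed c the model is linear in (a, b), so c is searched
#' on a log-spaced grid and refined by golden-section search. Deterministic.
#'
#' @param ages patient ages (years), >= 4 points with >= 3 distinct ages.
#' @param burdens pre-duplication substitution burdens.
#' @return an object of class `age_curve` with `a`, `b`, `c`, `sse` and
#'   `degenerate` (TRUE when the data are constant and b is pinned to 0).
#' @export
fit_age_curve <- function(ages, burdens) {
  stopifnot(length(ages) == length(burdens))
  if (length(ages) < 4 || length(unique(ages)) < 3) {
    stop("need >= 4 points with >= 3 distinct ages")
  }
  if (stats::sd(burdens) == 0) {
    return(structure(list(a = mean(burdens), b = 0, c = 0, sse = 0,
                          degenerate = TRUE), class = "age_curve"))
  }
  fit_c <- function(cc) {
    x <- exp(cc * ages)
    f <- stats::lm.fit(cbind(1, x), burdens)
    list(sse = sum(f$residuals^2), a = f$coefficients[1], b = f$coefficients[2])
  }
  grid <- -exp(seq(log(1e-4), log(2), length.out = 200))
  sses <- vapply(grid, function(cc) fit_c(cc)$sse, numeric(1))
  best <- which.min(sses)
  lo <- grid[min(best + 1L, length(grid))]   # grid is decreasing in |c|
  hi <- grid[max(best - 1L, 1L)]
  opt <- stats::optimize(function(cc) fit_c(cc)$sse,
                         interval = sort(c(lo, hi)), tol = 1e-10)
  f <- fit_c(opt$minimum)
  structure(list(a = unname(f$a), b = unname(f$b), c = opt$minimum,
                 sse = f$sse, degenerate = FALSE), class = "age_curve")
}

#' @export
print.age_curve <- function(x, ...) {
  cat(sprintf("age_curve: burden = %.2f + %.2f * exp(%.4f * age)\n",
              x$a, x$b, x$c))
  invisible(x)
}

#' @export
predict.age_curve <- function(object, newdata, ...) {
  ages <- if (is.data.frame(newdata)) newdata$age else newdata
  object$a + object$b * exp(object$c * ages)
}

#' Classify focal amplification and deletion candidates
#'
#' Focal amplifications are segments < 1 Mb whose total copy number reaches
#' 5 (average ploidy < 2.7) or 9 (ploidy >= 2.7) intact copies. Focal
#' deletions share the size and ploidy cut-offs with total copy number 0 or
#' below ploidy minus 2.7. Segments of 1-10 Mb that meet the copy threshold
#' are reported in a separate "gain" tier. Genes are matched to qualifying
#' segments by overlap.
#'
#' @param segments data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive), `total_cn`.
#' @param average_ploidy sample average ploidy.
#' @param genes optional data.frame with `gene`, `chrom`, `start`, `end`.
#' @return data.frame of qualifying segments with `call` in
#'   {"amplification", "deletion", "gain"} and, when `genes` given, a
#'   comma-separated `genes` column.
#' @export
classify_focal_events <- function(segments, average_ploidy, genes = NULL) {
  stopifnot(all(c("chrom", "start", "end", "total_cn") %in% names(segments)))
  span <- segments$end - segments$start + 1
  amp_min <- if (average_ploidy < 2.7) 5 else 9
  call <- rep(NA_character_, nrow(segments))
  call[span < 1e6 & segments$total_cn >= amp_min] <- "amplification"
  call[span >= 1e6 & span <= 10e6 & segments$total_cn >= amp_min] <- "gain"
  call[span < 1e6 &
       (segments$total_cn == 0 | segments$total_cn < average_ploidy - 2.7)] <-
    "deletion"
  out <- segments[!is.na(call), , drop = FALSE]
  out$call <- call[!is.na(call)]
  if (!is.null(genes) && nrow(out)) {
    out$genes <- vapply(seq_len(nrow(out)), function(i) {
      hit <- genes$chrom == out$chrom[i] &
        genes$end >= out$start[i] & genes$start <= out$end[i]
      paste(genes$gene[hit], collapse = ",")
    }, character(1))
  }
  out
}
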