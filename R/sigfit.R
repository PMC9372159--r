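# 96-channel substitution spectra and signature attribution by
# expectation-maximisation against a reference catalogue.
#
# Channel convention: pyrimidine-centred base changes in six blocks
# (C>A, C>G, C>T, T>A, T>C, T>G), each with 16 trinucleotide contexts
# ordered alphabetically by 5' then 3' flank, e.g. "A[C>G]G". Purine-centred
# mutations are reverse-complemented into this frame.

.bases <- c("A", "C", "G", "T")
.sub_classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The fixed 96-channel order
#'
#' @return character vector of 96 channel names such as "A[C>G]G".
#' @export
channels_96 <- function() {
  unlist(lapply(.sub_classes, function(s) {
    as.vector(t(outer(.bases, .bases, function(f, t3)
      paste0(f, "[", s, "]", t3))))
  }))
}

#' @noRd
.revcomp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

#' Parse channel names into ref/alt and flanking bases
#'
#' @param channel character vector like "A[C>G]G".
#' @return data.frame with `fivep`, `ref`, `alt`, `threep`.
#' @export
parse_channel <- function(channel) {
  m <- regmatches(channel,
                  regexec("^([ACGT])\\[([CT])>([ACGT])\\]([ACGT])$", channel))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) stop("malformed channel(s): ",
                     paste(unique(channel[bad]), collapse = ", "))
  data.frame(fivep = vapply(m, `[`, character(1), 2L),
             ref = vapply(m, `[`, character(1), 3L),
             alt = vapply(m, `[`, character(1), 4L),
             threep = vapply(m, `[`, character(1), 5L))
}

#' Tabulate a 96-channel substitution spectrum
#'
#' Accepts either precomputed channel strings or ref/alt bases with
#' flanking bases; purine-centred (A/G reference) mutations are
#' reverse-complemented into the pyrimidine frame. Mutations containing
#' ambiguous bases (N) are skipped and counted in the `skipped` attribute.
#'
#' @param mutations data.frame with a `channel` column, or with `ref`,
#'   `alt`, `fivep`, `threep` base columns.
#' @return named integer vector of length 96 (class `spectrum_96`) whose
#'   total equals the number of usable input mutations.
#' @export
tabulate_96 <- function(mutations) {
  if (!is.data.frame(mutations)) stop("'mutations' must be a data.frame")
  if ("channel" %in% names(mutations)) {
    ch <- mutations$channel
  } else {
    need <- c("ref", "alt", "fivep", "threep")
    if (!all(need %in% names(mutations))) {
      stop("need a 'channel' column or columns ", paste(need, collapse = ", "))
    }
    ref <- toupper(mutations$ref); alt <- toupper(mutations$alt)
    f5 <- toupper(mutations$fivep); f3 <- toupper(mutations$threep)
    ok <- ref %in% .bases & alt %in% .bases & f5 %in% .bases & f3 %in% .bases
    flip <- ok & ref %in% c("A", "G")
    r <- ref; a <- alt; l <- f5; t3 <- f3
    r[flip] <- .revcomp_base(ref[flip])
    a[flip] <- .revcomp_base(alt[flip])
    l[flip] <- .revcomp_base(f3[flip])   # flanks swap on the reverse strand
    t3[flip] <- .revcomp_base(f5[flip])
    ch <- rep(NA_character_, nrow(mutations))
    ch[ok] <- paste0(l[ok], "[", r[ok], ">", a[ok], "]", t3[ok])
  }
  chans <- channels_96()
  usable <- !is.na(ch) & ch %in% chans
  spec <- table(factor(ch[usable], levels = chans))
  out <- structure(as.integer(spec), names = chans, class = "spectrum_96")
  attr(out, "skipped") <- sum(!usable)
  out
}

#' @export
print.spectrum_96 <- function(x, ...) {
  cat(sprintf("spectrum_96: %d substitutions", sum(x)))
  sk <- attr(x, "skipped")
  if (!is.null(sk) && sk > 0) cat(sprintf(" (%d skipped)", sk))
  cat("; top channels:",
      paste(names(sort(unclass(x), decreasing = TRUE))[1:3], collapse = ", "),
      "\n")
  invisible(x)
}

#' Bundled toy signature catalogue
#'
#' A small synthetic catalogue for tests and simulations (real catalogues
#' load from TSV with [read_catalogue()]): `SBS1`-like (C>T at NpCpG),
#' `SBS5`-like (flat, clock-like), `SBS18`-like (C>A-dominated), and
#' `SBSA`, a synthetic component sharply peaked at the A[C>G]G channel.
#' Each column sums to 1.
#'
#' @return 96 x 4 matrix of channel probabilities.
#' @export
toy_signature_catalogue <- function() {
  chans <- channels_96()
  parsed <- parse_channel(chans)
  sub <- paste0(parsed$ref, ">", parsed$alt)
  sbs1 <- ifelse(sub == "C>T" & parsed$threep == "G", 1, 0.01)
  sbs5 <- rep(1, 96) + 0.2 * sin(seq_len(96))   # gently uneven flat profile
  sbs18 <- ifelse(sub == "C>A", 1, 0.02)
  sbsa <- ifelse(chans == "A[C>G]G", 30,
                 ifelse(sub == "C>G" & parsed$fivep == "A", 1, 0.01))
  cat <- cbind(SBS1 = sbs1, SBS5 = sbs5, SBS18 = sbs18, SBSA = sbsa)
  rownames(cat) <- chans
  sweep(cat, 2L, colSums(cat), "/")
}

#' Read a signature catalogue from TSV
#'
#' Expects a channel column (first column or named `channel`/`Type`) and
#' one numeric column per signature; columns are renormalised to sum to 1.
#'
#' @param path TSV file path.
#' @return 96 x S probability matrix with channel rownames.
#' @export
read_catalogue <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  chan_col <- intersect(c("channel", "Type", "MutationType"), names(df))
  chan_col <- if (length(chan_col)) chan_col[1L] else names(df)[1L]
  chans <- df[[chan_col]]
  mat <- as.matrix(df[, setdiff(names(df), chan_col), drop = FALSE])
  rownames(mat) <- chans
  mat <- mat[channels_96(), , drop = FALSE]
  sweep(mat, 2L, colSums(mat), "/")
}

#' Attribute a spectrum to reference signatures by EM
#'
#' Fits the multinomial mixture x ~ sum_s w_s * P[, s] by
#' expectation-maximisation with a uniform deterministic initialisation.
#' The log-likelihood is non-decreasing across iterations; convergence is
#' declared when the largest exposure change drops below `tol`. Effectively
#' collinear signature pairs in the catalogue (cosine similarity > 0.999)
#' are flagged: their summed exposure is identifiable but the split is not.
#'
#' @param spectrum a `spectrum_96` (or any non-negative 96-vector) with
#'   positive total.
#' @param catalogue 96 x S matrix of channel probabilities.
#' @param tol convergence tolerance on exposures; default 1e-8.
#' @param max_iter maximum EM iterations; default 10000.
#' @return list with `exposures` (named, non-negative, summing to 1),
#'   `loglik` (per-iteration trace), `iterations`, `converged`, and
#'   `degenerate_pairs` (matrix of flagged collinear signature pairs).
#' @export
em_attribution <- function(spectrum, catalogue, tol = 1e-8, max_iter = 10000) {
  x <- as.numeric(spectrum)
  if (length(x) != nrow(catalogue)) {
    stop("spectrum length must match catalogue rows")
  }
  if (sum(x) <= 0) stop("spectrum total must be > 0")
  if (ncol(catalogue) < 1L) stop("catalogue is empty")
  P <- sweep(catalogue, 2L, colSums(catalogue), "/")
  S <- ncol(P)
  cos_mat <- crossprod(sweep(P, 2L, sqrt(colSums(P^2)), "/"))
  deg <- which(cos_mat > 0.999 & upper.tri(cos_mat), arr.ind = TRUE)
  degenerate_pairs <- if (nrow(deg)) {
    cbind(colnames(P)[deg[, 1L]], colnames(P)[deg[, 2L]])
  } else matrix(character(0), ncol = 2L)
  w <- rep(1 / S, S)
  loglik <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mix <- as.vector(P %*% w)
    loglik <- c(loglik, sum(x[mix > 0] * log(mix[mix > 0])))
    resp <- sweep(P, 2L, w, "*") / pmax(mix, 1e-300)   # 96 x S
    w_new <- as.vector(crossprod(resp, x)) / sum(x)
    if (max(abs(w_new - w)) < tol) {
      w <- w_new
      converged <- TRUE
      break
    }
    w <- w_new
  }
  names(w) <- colnames(P)
  list(exposures = w, loglik = loglik, iterations = length(loglik),
       converged = converged, degenerate_pairs = degenerate_pairs)
}

#' Cosine similarity between spectra or signatures
#'
#' @param a,b non-negative numeric vectors of equal length; neither may be
#'   all zero.
#' @return cosine similarity in [0, 1].
#' @export
cosine_sim <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vectors")
  sum(a * b) / (na * nb)
}

#' Per-patient spectrum over unique substitutions
#'
#' Tabulates one spectrum per patient from the unique substitutions across
#' the patient's biopsies (counting each substitution once prevents
#' double-counting shared truncal mutations).
#'
#' @param variants data.frame with `patient`, `mut_id`, `channel`.
#' @return named list of `spectrum_96` per patient.
#' @export
patient_spectra <- function(variants) {
  stopifnot(all(c("patient", "mut_id", "channel") %in% names(variants)))
  lapply(split(variants, variants$patient), function(v) {
    tabulate_96(v[!duplicated(v$mut_id), , drop = FALSE])
  })
}
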