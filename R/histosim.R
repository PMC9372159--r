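# Pairwise genetic and transcriptomic similarity of microdissections
# within a tumour, the label-swap permutation test of histology-clone
# concordance, and the chromothripsis transcriptional variance test.

#' Construct a similarity matrix object
#'
#' @param scores symmetric biopsy x biopsy numeric matrix with dimnames.
#' @param histology named histology label per biopsy.
#' @param modality "genetic" or "transcriptomic".
#' @return an object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(scores, histology,
                              modality = c("genetic", "transcriptomic")) {
  modality <- match.arg(modality)
  stopifnot(is.matrix(scores), nrow(scores) == ncol(scores),
            length(histology) == nrow(scores))
  if (is.null(names(histology))) names(histology) <- rownames(scores)
  structure(list(scores = scores, histology = histology,
                 modality = modality), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix (%s): %d biopsies, %d histologies\n",
              x$modality, nrow(x$scores), length(unique(x$histology))))
  invisible(x)
}

#' Extract off-diagonal pairs and their intra/inter labels
#' @noRd
.sim_pairs <- function(sim) {
  n <- nrow(sim$scores)
  ij <- which(upper.tri(sim$scores), arr.ind = TRUE)
  data.frame(i = ij[, 1L], j = ij[, 2L],
             score = sim$scores[ij],
             intra = sim$histology[ij[, 1L]] == sim$histology[ij[, 2L]])
}

#' Genetic similarity of biopsy pairs from a clone tree
#'
#' The score of a biopsy pair is the number of substitutions in clusters
#' present in both biopsies divided by the mean of the two biopsies' total
#' burdens (substitutions in clusters present in each); a cluster is
#' present where its CCF is strictly greater than `presence_ccf`. Biopsies
#' with no present clusters yield `NA` scores and are reported.
#'
#' @param tree a `clone_tree` (or `ccf_clusters`) whose cluster table has
#'   `n_subs` and per-biopsy `ccf_` columns.
#' @param histology named histology label per biopsy (names matching the
#'   `ccf_` suffixes).
#' @param presence_ccf presence threshold; default 0.1.
#' @return a `similarity_matrix` with genetic scores in [0, 1].
#' @export
genetic_similarity <- function(tree, histology, presence_ccf = 0.1) {
  cl <- if (inherits(tree, "clone_tree")) tree$clusters else tree$clusters
  ccf_cols <- grep("^ccf_", names(cl), value = TRUE)
  biopsies <- sub("^ccf_", "", ccf_cols)
  present <- as.matrix(cl[, ccf_cols, drop = FALSE]) > presence_ccf
  burden <- colSums(cl$n_subs * present)
  n <- length(biopsies)
  scores <- matrix(NA_real_, n, n, dimnames = list(biopsies, biopsies))
  empty <- burden == 0
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (empty[a] || empty[b]) next
    shared <- sum(cl$n_subs[present[, a] & present[, b]])
    scores[a, b] <- shared / mean(c(burden[a], burden[b]))
  }
  if (any(empty)) {
    warning("biopsies with no present clusters: ",
            paste(biopsies[empty], collapse = ", "))
  }
  similarity_matrix(scores, histology[biopsies], "genetic")
}

#' Transcriptomic similarity of biopsy pairs
#'
#' Pearson correlation of log2(TPM + 1) between each pair of libraries over
#' protein-coding genes outside the exclusion sets (haemoglobin,
#' immunoglobulin, cycling, housekeeping).
#'
#' @param expr an [expression_study()].
#' @param libraries optional library subset (default all tumour libraries).
#' @return a `similarity_matrix` with scores in [-1, 1].
#' @export
transcriptomic_similarity <- function(expr, libraries = NULL) {
  stopifnot(inherits(expr, "expression_study"))
  if (is.null(libraries)) {
    libraries <- expr$samples$sample[!expr$samples$is_normal_tubule]
  }
  keep <- expr$genes$biotype == "protein_coding" &
    (expr$genes$exclusion_set == "" | is.na(expr$genes$exclusion_set))
  if (sum(keep) < 2L) stop("fewer than 2 retained genes")
  lt <- log2(expr$tpm[keep, libraries, drop = FALSE] + 1)
  scores <- stats::cor(lt, method = "pearson")
  hist <- expr$samples$histology[match(libraries, expr$samples$sample)]
  names(hist) <- libraries
  similarity_matrix(scores, hist, "transcriptomic")
}

#' Label-swap permutation test of intra- vs inter-histology similarity
#'
#' The statistic is median(intra-histology scores) - median(inter-histology
#' scores) over all biopsy pairs. The null is built by permuting the
#' intra/inter labels over the pairwise comparisons. When the number of
#' distinct label assignments choose(n_pairs, n_intra) does not exceed
#' `n_perm`, every assignment is enumerated and
#' p = (1 + #\{alternatives >= observed\}) / #assignments; otherwise
#' `n_perm` random swaps give p = (1 + #\{null >= observed\}) /
#' (n_perm + 1). Ties count as exceedances. One-sided: large positive
#' differences indicate histology-clone concordance.
#'
#' @param sim a `similarity_matrix`.
#' @param n_perm random permutations; default 1000.
#' @param seed integer seed (sampled mode).
#' @return list with `p`, `observed`, `mode` ("exhaustive"/"sampled"),
#'   `n_assignments` (exhaustive) or `n_perm`, and the pair counts.
#' @export
label_swap_test <- function(sim, n_perm = 1000, seed = NULL) {
  stopifnot(inherits(sim, "similarity_matrix"))
  pairs <- .sim_pairs(sim)
  pairs <- pairs[!is.na(pairs$score), , drop = FALSE]
  n_intra <- sum(pairs$intra); n_inter <- sum(!pairs$intra)
  if (n_intra == 0L || n_inter == 0L) {
    stop("need at least one intra- and one inter-histology pair")
  }
  stat <- function(intra) {
    stats::median(pairs$score[intra]) - stats::median(pairs$score[!intra])
  }
  observed <- stat(pairs$intra)
  n_pairs <- nrow(pairs)
  n_assign <- choose(n_pairs, n_intra)
  if (n_assign <= n_perm) {
    combos <- utils::combn(n_pairs, n_intra)
    stats_all <- apply(combos, 2L, function(ix) {
      intra <- rep(FALSE, n_pairs); intra[ix] <- TRUE
      stat(intra)
    })
    is_obs <- apply(combos, 2L, function(ix)
      identical(sort(ix), sort(which(pairs$intra))))
    p <- (1 + sum(stats_all[!is_obs] >= observed)) / n_assign
    list(p = p, observed = observed, mode = "exhaustive",
         n_assignments = n_assign, n_intra = n_intra, n_inter = n_inter)
  } else {
    null_stats <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        intra <- rep(FALSE, n_pairs)
        intra[sample.int(n_pairs, n_intra)] <- TRUE
        stat(intra)
      }, numeric(1))
    })
    p <- (1 + sum(null_stats >= observed)) / (n_perm + 1)
    list(p = p, observed = observed, mode = "sampled", n_perm = n_perm,
         n_intra = n_intra, n_inter = n_inter)
  }
}

#' Chromothripsis transcriptional variance test
#'
#' Tests whether a focal tumour's intra-histology transcriptomic
#' correlations are more variable (more transcriptionally heterogeneous)
#' than random same-size subsets of the correlations pooled across
#' tumours: the null distribution is the variance of `n_iter` random
#' k-subsets of the pool (k = number of focal correlations), and
#' p = fraction of null variances >= the observed variance (one-sided).
#' When the pool admits fewer subsets than `n_iter`, all subsets are
#' enumerated.
#'
#' @param focal numeric vector of the focal tumour's correlations.
#' @param pool numeric vector of correlations pooled across tumours.
#' @param n_iter random subsets; default 1000.
#' @param seed integer seed.
#' @return list with `p`, `observed`, `mode`, `k`.
#' @export
chromothripsis_variance_test <- function(focal, pool, n_iter = 1000,
                                         seed = NULL) {
  k <- length(focal)
  if (k < 2L) stop("need >= 2 focal correlations for a variance")
  if (length(pool) < k) {
    stop(sprintf("pool (%d values) smaller than focal set (%d)",
                 length(pool), k))
  }
  observed <- stats::var(focal)
  n_subsets <- choose(length(pool), k)
  if (n_subsets <= n_iter) {
    combos <- utils::combn(length(pool), k)
    null_vars <- apply(combos, 2L, function(ix) stats::var(pool[ix]))
    mode <- "exhaustive"
  } else {
    null_vars <- with_seed(seed, {
      vapply(seq_len(n_iter), function(i)
        stats::var(pool[sample.int(length(pool), k)]), numeric(1))
    })
    mode <- "sampled"
  }
  list(p = mean(null_vars >= observed), observed = observed,
       mode = mode, k = k)
}
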