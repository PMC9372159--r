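# Shared builders for small in-code fixtures.

# A ccf_clusters object built directly from a cluster table (bypassing the
# sampler) so tree logic can be tested on exact CCFs.
make_clusters <- function(n_subs, ccf, assignment = NULL) {
  ccf <- as.matrix(ccf)
  colnames(ccf) <- paste0("ccf_", colnames(ccf) %||% paste0("b", seq_len(ncol(ccf))))
  cl <- data.frame(cluster = seq_along(n_subs), n_subs = n_subs)
  cl <- cbind(cl, as.data.frame(ccf))
  structure(list(clusters = cl,
                 assignment = assignment %||% rep(seq_along(n_subs), n_subs),
                 ccf = NULL),
            class = "ccf_clusters")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Symmetric similarity matrix from upper-triangle scores.
make_similarity <- function(upper, n, histology, modality = "genetic") {
  sc <- matrix(0, n, n)
  sc[upper.tri(sc)] <- upper
  sc <- sc + t(sc)
  diag(sc) <- 1
  dimnames(sc) <- list(names(histology), names(histology))
  similarity_matrix(sc, histology, modality)
}

small_cohort <- function(seed = 1, ...) {
  simulate_cohort(cohort_config(n_patients = 1, mutation_rate = 300,
                                n_genes = 400, seed = seed, ...))
}
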