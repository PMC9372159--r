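# Synthetic multi-region germ-cell-tumour cohort simulator with full
# ground truth: near-monoclonal microbiopsies, whole-genome duplication at
# a controllable mutation time, allele-specific copy-number segments,
# subclone clusters shared across biopsies of mixed histology,
# histology-specific expression programs with a chromosome-arm dosage
# effect, trinucleotide-resolved substitution spectra, and an unmatched
# normal panel.

#' Autosomal chromosome-arm table (GRCh37 scale)
#'
#' Approximate arm boundaries for the 22 autosomes used to place simulated
#' copy-number segments and genes. Coordinates are 1-based inclusive.
#'
#' @return data.frame with `chrom`, `arm`, `start`, `end`, `length`.
#' @export
genome_arms <- function() {
  len <- c(249.25, 243.2, 198.0, 191.2, 180.9, 171.1, 159.1, 146.4, 141.2,
           135.5, 135.0, 133.9, 115.2, 107.3, 102.5, 90.4, 81.2, 78.1,
           59.1, 63.0, 48.1, 51.3) * 1e6
  cen <- c(125, 93.3, 91, 50.4, 48.4, 61, 59.9, 45.6, 49, 40.2, 53.7, 35.8,
           17.9, 17.6, 19, 36.6, 24, 17.2, 26.5, 27.5, 13.2, 14.7) * 1e6
  chrom <- rep(as.character(1:22), each = 2L)
  arm <- paste0(chrom, rep(c("p", "q"), times = 22L))
  start <- as.numeric(rbind(1, cen + 1))
  end <- as.numeric(rbind(cen, len))
  data.frame(chrom = chrom, arm = arm, start = start, end = end,
             length = end - start + 1)
}

#' Configure a synthetic cohort
#'
#' Defaults emulate a postpubertal germ-cell-tumour cohort: near-monoclonal
#' laser-capture microbiopsies (major clone CCF about 0.96), very early
#' whole-genome duplication (mutation time 0.02), duplicated-genome
#' copy-number states, roughly 1,400 truncal substitutions (about 0.49 per
#' Mb over the autosomes), sequencing depth 30x, a clock-dominated
#' signature mixture with a small A[C>G]G-peaked component, and a doubled
#' 12p dosage effect on expression. Set `wgd_time` large (e.g. 0.5) for a
#' prepubertal-like late-duplication regime.
#'
#' @param n_patients number of patients.
#' @param ages patient ages in years (recycled).
#' @param wgd_time whole-genome duplication mutation time in [0, 1)
#'   (recycled per patient).
#' @param n_biopsies microbiopsies per patient.
#' @param histologies histology label per biopsy (recycled to
#'   `n_biopsies`).
#' @param depth mean sequencing depth per biopsy.
#' @param purity tumour purity per biopsy in (0, 1] (recycled).
#' @param n_clusters clone clusters per patient (including the trunk).
#' @param mutation_rate expected truncal substitutions per unit mutation
#'   time.
#' @param trunk_fraction expected fraction of mutations in the trunk.
#' @param signature_mix named weights over the bundled signature catalogue,
#'   summing to 1.
#' @param dosage_arm chromosome arm carrying the expression dosage effect.
#' @param dosage_multiplier expression gain multiplier on `dosage_arm`.
#' @param state_probs named probabilities of segment copy states.
#' @param n_genes genes in the expression study.
#' @param expression_dispersion negative-binomial gene dispersion.
#' @param n_normal_tubules normal seminiferous-tubule RNA libraries.
#' @param major_ccf CCF of a biopsy's major clone (near-monoclonality).
#' @param seed integer seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 2,
                          ages = c(30, 25),
                          wgd_time = 0.02,
                          n_biopsies = 4,
                          histologies = c("embryonal_carcinoma",
                                          "embryonal_carcinoma",
                                          "yolk_sac_tumour",
                                          "teratoma"),
                          depth = 30,
                          purity = 0.95,
                          n_clusters = 3,
                          mutation_rate = 1400,
                          trunk_fraction = 0.75,
                          signature_mix = c(SBS1 = 0.2, SBS5 = 0.65,
                                            SBS18 = 0.1, SBSA = 0.05),
                          dosage_arm = "12p",
                          dosage_multiplier = 2,
                          state_probs = c("2+2" = 0.45, "2+1" = 0.25,
                                          "2+0" = 0.15, "3+2" = 0.15),
                          n_genes = 2000,
                          expression_dispersion = 0.2,
                          n_normal_tubules = 4,
                          major_ccf = 0.96,
                          seed = 1L) {
  fail <- function(field, msg) stop(sprintf("invalid '%s': %s", field, msg),
                                    call. = FALSE)
  if (n_patients < 1) fail("n_patients", "need >= 1 patient")
  if (n_biopsies < 1) fail("n_biopsies", "need >= 1 biopsy")
  if (any(wgd_time < 0 | wgd_time >= 1)) fail("wgd_time", "must lie in [0, 1)")
  if (any(purity <= 0 | purity > 1)) fail("purity", "must lie in (0, 1]")
  if (depth <= 0) fail("depth", "must be > 0")
  if (n_clusters < 1) fail("n_clusters", "need >= 1 cluster")
  if (mutation_rate < 0) fail("mutation_rate", "must be >= 0")
  if (trunk_fraction <= 0 || trunk_fraction > 1) {
    fail("trunk_fraction", "must lie in (0, 1]")
  }
  if (abs(sum(signature_mix) - 1) > 1e-9) {
    fail("signature_mix", "weights must sum to 1")
  }
  if (is.null(names(signature_mix))) fail("signature_mix", "must be named")
  if (abs(sum(state_probs) - 1) > 1e-9) fail("state_probs", "must sum to 1")
  if (dosage_multiplier <= 0) fail("dosage_multiplier", "must be > 0")
  structure(list(
    n_patients = as.integer(n_patients),
    ages = rep_len(ages, n_patients),
    wgd_time = rep_len(wgd_time, n_patients),
    n_biopsies = as.integer(n_biopsies),
    histologies = rep_len(histologies, n_biopsies),
    depth = depth, purity = rep_len(purity, n_biopsies),
    n_clusters = as.integer(n_clusters),
    mutation_rate = mutation_rate, trunk_fraction = trunk_fraction,
    signature_mix = signature_mix,
    dosage_arm = dosage_arm, dosage_multiplier = dosage_multiplier,
    state_probs = state_probs, n_genes = as.integer(n_genes),
    expression_dispersion = expression_dispersion,
    n_normal_tubules = as.integer(n_normal_tubules),
    major_ccf = major_ccf, seed = as.integer(seed)
  ), class = "cohort_config")
}

# Multiplicity of a pre-duplication mutation by copy state and destined
# allele ("major"/"minor"). 0 means the mutation is lost (invisible).
.pre_dup_multiplicity <- function(state, allele) {
  m <- ifelse(allele == "major", 2L,
              ifelse(state == "2+2", 2L,
                     ifelse(state == "2+1", 1L,
                            ifelse(state == "2+0", 0L, 2L))))
  as.integer(m)
}

#' Simulate a synthetic multi-region cohort
#'
#' Draws, per patient: clonal allele-specific copy-number segments (one per
#' autosome arm, whole-genome duplicated), a clone tree rooted at a trunk,
#' substitutions placed in mutation time relative to the duplication (a
#' mutation before `wgd_time` on a duplicated allele has multiplicity 2;
#' mutations on the lost allele of 2+0 segments are recorded but
#' invisible), per-biopsy read counts with alt ~ Binomial(depth, expected
#' VAF) where expected VAF = m * purity * CCF / (purity * CNt +
#' 2 (1 - purity)), one matched normal with panel-level error noise,
#' trinucleotide channels drawn from the configured signature mixture, and
#' a gene-level expression study with histology programs, a dosage-arm
#' multiplier, and negative-binomial noise. Identical config and seed give
#' identical output.
#'
#' @param config a [cohort_config()].
#' @return an object of class `synthetic_cohort`: `calls` (a
#'   `mutation_call_set` with `variants`, `alt`, `depth`, `samples`),
#'   `segments` (per-biopsy segment table), `expression` (an
#'   [expression_study()]), `truth` (ground truth: `mutations`, `tree`,
#'   `ccf`, `expression_fc`, `n_pre_dup` per patient), and `profiles`
#'   (per-biopsy [sample_profile()] list).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  catalogue <- toy_signature_catalogue()
  miss <- setdiff(names(config$signature_mix), colnames(catalogue))
  if (length(miss)) {
    stop("invalid 'signature_mix': unknown signature(s) ",
         paste(miss, collapse = ", "))
  }
  arms <- genome_arms()
  with_seed(config$seed, {
    all_variants <- list(); all_segments <- list()
    truth_mut <- list(); truth_tree <- list(); truth_ccf <- list()
    alt_cols <- list(); depth_cols <- list(); samples_df <- list()
    n_pre_dup <- numeric(config$n_patients)
    names(n_pre_dup) <- paste0("P", seq_len(config$n_patients))

    for (p in seq_len(config$n_patients)) {
      pid <- paste0("P", p)
      wgd_t <- config$wgd_time[p]
      # --- clonal copy-number states, one segment per arm, WGD-consistent
      states <- sample(names(config$state_probs), nrow(arms), replace = TRUE,
                       prob = config$state_probs)
      if (config$dosage_arm %in% arms$arm &&
          any(names(config$state_probs) == "3+2")) {
        states[arms$arm == config$dosage_arm] <- "3+2"  # recurrent 12p gain
      }
      major <- as.integer(sub("\\+.*", "", states))
      minor <- as.integer(sub(".*\\+", "", states))
      cnt_arm <- major + minor

      # --- clone tree: cluster 1 is the trunk
      K <- config$n_clusters
      parent <- c(NA_integer_,
                  if (K > 1) vapply(2:K, function(k)
                    sample.int(k - 1L, 1L), integer(1)))
      depth_in_tree <- integer(K)
      for (k in seq_len(K)) {
        d <- 0L; a <- parent[k]
        while (!is.na(a)) { d <- d + 1L; a <- parent[a] }
        depth_in_tree[k] <- d
      }
      tips <- setdiff(seq_len(K), parent[!is.na(parent)])
      # per-biopsy CCFs: each biopsy is a patch dominated by one tip clone
      patch <- sample(tips, config$n_biopsies, replace = TRUE)
      on_path <- function(k, tip) {
        a <- tip
        while (!is.na(a)) { if (a == k) return(TRUE); a <- parent[a] }
        FALSE
      }
      ccf_kb <- matrix(0, K, config$n_biopsies)
      for (b in seq_len(config$n_biopsies)) {
        for (k in seq_len(K)) {
          if (on_path(k, patch[b])) {
            ccf_kb[k, b] <- config$major_ccf^depth_in_tree[k]
          }
        }
      }
      ccf_kb[1L, ] <- 1  # trunk is fully clonal in every biopsy

      # --- mutation counts per cluster
      n_trunk <- stats::rpois(1L, config$mutation_rate)
      n_sub <- if (K > 1) stats::rpois(
        K - 1L, config$mutation_rate *
          (1 / config$trunk_fraction - 1) / (K - 1L)) else integer(0)
      n_per_cluster <- c(n_trunk, n_sub)
      n_mut <- sum(n_per_cluster)
      if (n_mut == 0) {
        # degenerate draw: the tree collapses to a bare truncal node
        K <- 1L
        parent <- NA_integer_
        ccf_kb <- matrix(1, 1L, config$n_biopsies)
        n_per_cluster <- 0L
      }

      if (n_mut > 0) {
        cluster <- rep(seq_len(K), n_per_cluster)
        is_trunk <- cluster == 1L
        # mutations accrue per chromosome copy: before the duplication the
        # genome carries 2 copies everywhere, afterwards CNt copies, so a
        # truncal mutation is pre-duplication with probability
        # wgd_t * W_pre / (wgd_t * W_pre + (1 - wgd_t) * W_post)
        w_pre <- arms$length * 2
        w_post <- arms$length * cnt_arm
        p_pre <- wgd_t * sum(w_pre) /
          (wgd_t * sum(w_pre) + (1 - wgd_t) * sum(w_post))
        pre <- is_trunk & stats::runif(n_mut) < p_pre
        time_mut <- ifelse(pre, stats::runif(n_mut, 0, wgd_t),
                           stats::runif(n_mut, wgd_t, 1))
        seg_idx <- integer(n_mut)
        if (any(pre)) seg_idx[pre] <- sample.int(nrow(arms), sum(pre),
                                                 replace = TRUE,
                                                 prob = w_pre)
        if (any(!pre)) seg_idx[!pre] <- sample.int(nrow(arms), sum(!pre),
                                                   replace = TRUE,
                                                   prob = w_post)
        allele <- ifelse(pre, sample(c("major", "minor"), n_mut,
                                     replace = TRUE), "major")
        mult <- ifelse(pre,
                       .pre_dup_multiplicity(states[seg_idx], allele), 1L)
        visible <- mult > 0L
        pos <- floor(stats::runif(n_mut, arms$start[seg_idx],
                                  arms$end[seg_idx] + 1))
        # trinucleotide channel from the signature mixture
        sig <- sample(names(config$signature_mix), n_mut, replace = TRUE,
                      prob = config$signature_mix)
        channel <- vapply(sig, function(s)
          sample(rownames(catalogue), 1L, prob = catalogue[, s]),
          character(1))
        parsed <- parse_channel(channel)
        mut_id <- sprintf("%s_m%04d", pid, seq_len(n_mut))

        truth_mut[[pid]] <- data.frame(
          patient = pid, mut_id = mut_id, cluster = cluster,
          time = time_mut, pre_dup = pre, multiplicity = as.integer(mult),
          state = states[seg_idx], visible = visible,
          chrom = arms$chrom[seg_idx], pos = pos, signature = sig,
          channel = channel)
        n_pre_dup[pid] <- sum(pre)

        # --- observed reads for visible mutations
        vis <- which(visible)
        n_vis <- length(vis)
        alt_mat <- matrix(0L, n_vis, config$n_biopsies + 1L)
        dep_mat <- matrix(0L, n_vis, config$n_biopsies + 1L)
        for (b in seq_len(config$n_biopsies)) {
          rho <- config$purity[b]
          cntv <- cnt_arm[seg_idx[vis]]
          f <- pmin(mult[vis] * rho * ccf_kb[cbind(cluster[vis], b)] /
                      (rho * cntv + 2 * (1 - rho)), 1)
          d <- stats::rpois(n_vis, config$depth)
          alt_mat[, b] <- stats::rbinom(n_vis, d, f)
          dep_mat[, b] <- d
        }
        d_norm <- stats::rpois(n_vis, config$depth)
        alt_mat[, config$n_biopsies + 1L] <-
          stats::rbinom(n_vis, d_norm, 1e-4)
        dep_mat[, config$n_biopsies + 1L] <- d_norm
        sample_ids <- c(sprintf("%s_b%d", pid, seq_len(config$n_biopsies)),
                        sprintf("%s_normal", pid))
        colnames(alt_mat) <- colnames(dep_mat) <- sample_ids
        rownames(alt_mat) <- rownames(dep_mat) <- mut_id[vis]

        all_variants[[pid]] <- data.frame(
          patient = pid, mut_id = mut_id[vis], chrom = arms$chrom[seg_idx[vis]],
          pos = pos[vis], ref = parsed$ref[vis], alt = parsed$alt[vis],
          channel = channel[vis], cluster = cluster[vis],
          multiplicity = as.integer(mult[vis]),
          cnt = cnt_arm[seg_idx[vis]])
        alt_cols[[pid]] <- alt_mat
        depth_cols[[pid]] <- dep_mat
      } else {
        truth_mut[[pid]] <- data.frame(
          patient = character(0), mut_id = character(0), cluster = integer(0),
          time = numeric(0), pre_dup = logical(0), multiplicity = integer(0),
          state = character(0), visible = logical(0), chrom = character(0),
          pos = numeric(0), signature = character(0), channel = character(0))
        all_variants[[pid]] <- data.frame(
          patient = character(0), mut_id = character(0), chrom = character(0),
          pos = numeric(0), ref = character(0), alt = character(0),
          channel = character(0), cluster = integer(0),
          multiplicity = integer(0), cnt = integer(0))
        n_pre_dup[pid] <- 0
        sample_ids <- c(sprintf("%s_b%d", pid, seq_len(config$n_biopsies)),
                        sprintf("%s_normal", pid))
        alt_cols[[pid]] <- depth_cols[[pid]] <-
          matrix(0L, 0L, length(sample_ids),
                 dimnames = list(NULL, sample_ids))
      }

      truth_tree[[pid]] <- data.frame(patient = pid, cluster = seq_len(K),
                                      parent = parent)
      truth_ccf[[pid]] <- data.frame(
        patient = pid,
        cluster = rep(seq_len(K), config$n_biopsies),
        biopsy = rep(sprintf("%s_b%d", pid, seq_len(config$n_biopsies)),
                     each = K),
        ccf = as.vector(ccf_kb))

      for (b in seq_len(config$n_biopsies)) {
        all_segments[[paste0(pid, "_b", b)]] <- data.frame(
          sample = sprintf("%s_b%d", pid, b), chrom = arms$chrom,
          start = arms$start, end = arms$end, major = major, minor = minor,
          frac = 1)
      }
      ploidy_p <- sum(cnt_arm * arms$length) / sum(arms$length)
      hom_p <- sum(arms$length[minor == 0]) / sum(arms$length)
      samples_df[[pid]] <- data.frame(
        sample = c(sprintf("%s_b%d", pid, seq_len(config$n_biopsies)),
                   sprintf("%s_normal", pid)),
        patient = pid,
        histology = c(config$histologies, "normal"),
        purity = c(config$purity, 0),
        ploidy = c(rep(ploidy_p, config$n_biopsies), 2),
        homozygous_fraction = c(rep(hom_p, config$n_biopsies), 0),
        depth = config$depth,
        is_normal = c(rep(FALSE, config$n_biopsies), TRUE))
    }

    expression <- .simulate_expression(config, arms)

    calls <- structure(list(
      variants = do.call(rbind, all_variants),
      alt = alt_cols, depth = depth_cols,
      samples = do.call(rbind, samples_df)), class = "mutation_call_set")
    rownames(calls$variants) <- NULL
    rownames(calls$samples) <- NULL
    segments <- do.call(rbind, all_segments)
    rownames(segments) <- NULL
    truth <- list(mutations = do.call(rbind, truth_mut),
                  tree = do.call(rbind, truth_tree),
                  ccf = do.call(rbind, truth_ccf),
                  expression_fc = expression$truth_fc,
                  n_pre_dup = n_pre_dup)
    rownames(truth$mutations) <- rownames(truth$tree) <-
      rownames(truth$ccf) <- NULL
    profiles <- lapply(split(calls$samples, calls$samples$sample),
                       function(s) sample_profile(
                         purity = max(s$purity, 1e-6), ploidy = s$ploidy,
                         coverage = s$depth,
                         homozygous_fraction = s$homozygous_fraction))
    structure(list(calls = calls, segments = segments,
                   expression = expression$study, truth = truth,
                   profiles = profiles, config = config),
              class = "synthetic_cohort")
  })
}

# Histology expression programs, dosage-arm multiplier, NB noise.
.simulate_expression <- function(config, arms) {
  n_genes <- config$n_genes
  seg_idx <- sample.int(nrow(arms), n_genes, replace = TRUE,
                        prob = arms$length)
  start <- floor(stats::runif(n_genes, arms$start[seg_idx],
                              arms$end[seg_idx] + 1))
  glen <- pmax(200, round(stats::rlnorm(n_genes, log(1500), 0.6)))
  band <- paste0(arms$arm[seg_idx],
                 ifelse(start < (arms$start[seg_idx] + arms$end[seg_idx]) / 2,
                        "1", "2"))
  biotype <- sample(c("protein_coding", "lncRNA"), n_genes, replace = TRUE,
                    prob = c(0.9, 0.1))
  exclusion <- sample(c("", "housekeeping", "cycling", "haemoglobin",
                        "immunoglobulin"), n_genes, replace = TRUE,
                      prob = c(0.94, 0.02, 0.02, 0.01, 0.01))
  genes <- data.frame(
    gene = sprintf("G%05d", seq_len(n_genes)), chrom = arms$chrom[seg_idx],
    start = start, end = start + glen - 1, strand = sample(c("+", "-"),
                                                           n_genes, TRUE),
    arm = arms$arm[seg_idx], cytoband = band, biotype = biotype,
    exclusion_set = exclusion, length = glen)

  base_mu <- stats::rlnorm(n_genes, log(20), 1.2)
  hist_labels <- unique(config$histologies)
  prog <- matrix(0, n_genes, length(hist_labels),
                 dimnames = list(genes$gene, hist_labels))
  for (h in hist_labels) {
    chosen <- sample.int(n_genes, min(400L, n_genes))
    prog[chosen, h] <- sample(c(-1.5, 1.5), length(chosen), replace = TRUE)
  }
  on_dosage <- genes$arm == config$dosage_arm

  sample_names <- character(0); histology <- character(0)
  tumour <- character(0); is_normal <- logical(0)
  for (p in seq_len(config$n_patients)) {
    pid <- paste0("P", p)
    sample_names <- c(sample_names,
                      sprintf("%s_b%d", pid, seq_len(config$n_biopsies)))
    histology <- c(histology, config$histologies)
    tumour <- c(tumour, rep(pid, config$n_biopsies))
    is_normal <- c(is_normal, rep(FALSE, config$n_biopsies))
  }
  if (config$n_normal_tubules > 0) {
    sample_names <- c(sample_names,
                      sprintf("NT_%d", seq_len(config$n_normal_tubules)))
    histology <- c(histology,
                   rep("seminiferous_tubule", config$n_normal_tubules))
    tumour <- c(tumour, rep("normal", config$n_normal_tubules))
    is_normal <- c(is_normal, rep(TRUE, config$n_normal_tubules))
  }
  counts <- matrix(0L, n_genes, length(sample_names),
                   dimnames = list(genes$gene, sample_names))
  size <- 1 / config$expression_dispersion
  for (s in seq_along(sample_names)) {
    lib <- stats::rlnorm(1, 0, 0.3)
    mu <- base_mu * lib
    if (!is_normal[s]) {
      mu <- mu * 2^prog[, histology[s]]
      mu[on_dosage] <- mu[on_dosage] * config$dosage_multiplier
    }
    counts[, s] <- stats::rnbinom(n_genes, mu = mu, size = size)
  }
  meta <- data.frame(sample = sample_names, histology = histology,
                     tumour = tumour, is_normal_tubule = is_normal)
  truth_fc <- data.frame(gene = genes$gene, prog,
                         dosage = ifelse(on_dosage,
                                         log2(config$dosage_multiplier), 0),
                         check.names = FALSE)
  list(study = expression_study(counts, genes, meta), truth_fc = truth_fc)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d patients, %d variants, %d biopsies/patient, %d genes\n",
    x$config$n_patients, nrow(x$calls$variants), x$config$n_biopsies,
    x$config$n_genes))
  invisible(x)
}

#' Simulate an unmatched normal panel
#'
#' Per-site alt counts follow a beta-binomial with the configured mean
#' error rate and overdispersion; depths are Poisson around `depth`.
#' Deterministic under `seed`; an error rate of zero yields all-zero alt
#' counts.
#'
#' @param n_samples number of panel samples (>= 2); the study used 250 for
#'   substitutions and 100 for indels.
#' @param depth mean sequencing depth.
#' @param error_rate per-site mean error fraction in [0, 0.5).
#' @param n_sites number of sites.
#' @param overdispersion beta-binomial overdispersion; default 0.002.
#' @param seed integer seed.
#' @return an object of class `panel_counts` with matrices `alt` and
#'   `depth` (sites x samples) and the generating parameters.
#' @export
simulate_panel <- function(n_samples, depth = 30, error_rate = 1e-3,
                           n_sites = 1000, overdispersion = 0.002,
                           seed = NULL) {
  if (n_samples < 2) stop("'n_samples' must be >= 2")
  if (error_rate < 0 || error_rate >= 0.5) {
    stop("'error_rate' must lie in [0, 0.5)")
  }
  with_seed(seed, {
    d <- matrix(stats::rpois(n_sites * n_samples, depth), n_sites, n_samples)
    a <- if (error_rate == 0) {
      matrix(0L, n_sites, n_samples)
    } else {
      matrix(rbetabinom(n_sites * n_samples, as.vector(d), error_rate,
                        overdispersion), n_sites, n_samples)
    }
    rownames(a) <- rownames(d) <- sprintf("site_%05d", seq_len(n_sites))
    colnames(a) <- colnames(d) <- sprintf("N%03d", seq_len(n_samples))
    structure(list(alt = a, depth = d, error_rate = error_rate,
                   overdispersion = overdispersion),
              class = "panel_counts")
  })
}

#' @export
print.panel_counts <- function(x, ...) {
  cat(sprintf("panel_counts: %d sites x %d samples, error rate %.2g\n",
              nrow(x$alt), ncol(x$alt), x$error_rate))
  invisible(x)
}
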