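# End-to-end orchestration of the analysis stages on a simulated cohort or
# on fixture files, with deterministic per-stage seeding and provenance
# headers on every output table.

#' Configure a pipeline run
#'
#' All thresholds default to the values used throughout the package:
#' minimum median alignment score 140, beta-binomial rescue at adjusted
#' p < 0.001, cluster presence at CCF > 0.1, cluster filters at < 1% of
#' substitutions or < 20 substitutions, segment eligibility at CI width
#' < 0.5, WGD rule ploidy >= 2.9 - 2 * homozygosity, near-baseline ploidy
#' +/- 0.5, 50-gene rolling window, 100,000 dosage draws, 1,000 label
#' swaps, genes expressed at >= 5 reads, libraries dropped under 1,000
#' expressed features.
#'
#' @param cohort_config a [cohort_config()] describing the cohort to
#'   simulate, or `NULL` when `input_dir` points at fixture files.
#' @param input_dir optional directory of fixtures from [write_fixtures()].
#' @param output_dir directory for stage reports.
#' @param stages character vector of stages to run, in dependency order
#'   from `c("simulate", "filter", "tree", "time", "similarity", "dosage",
#'   "signatures")`.
#' @param seed master seed; per-stage seeds are derived from it by stage
#'   name so stages are individually reproducible.
#' @param panel_samples unmatched normal panel size; default 250.
#' @param rescue_alpha adjusted p threshold for presence calls.
#' @param presence_ccf cluster presence threshold.
#' @param cluster_min_fraction,cluster_min_count cluster filters.
#' @param cluster_iters,cluster_burnin Gibbs sweeps for CCF clustering.
#' @param n_perm label swaps for the similarity test.
#' @param n_draws dosage permutation draws.
#' @param near_baseline near-baseline ploidy half-width.
#' @param dosage_arm target arm for the dosage test.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_config = NULL, input_dir = NULL,
                            output_dir = tempfile("clonehist_run_"),
                            stages = c("simulate", "filter", "tree", "time",
                                       "similarity", "dosage", "signatures"),
                            seed = 1L, panel_samples = 250,
                            rescue_alpha = 0.001, presence_ccf = 0.1,
                            cluster_min_fraction = 0.01,
                            cluster_min_count = 20,
                            cluster_iters = 400, cluster_burnin = 100,
                            n_perm = 1000, n_draws = 100000,
                            near_baseline = 0.5, dosage_arm = "12p") {
  if (is.null(cohort_config) && is.null(input_dir)) {
    stop("provide either 'cohort_config' or 'input_dir'")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' @noRd
.config_hash <- function(config) {
  h <- 2166136261
  for (b in utf8ToInt(paste(deparse(config), collapse = ""))) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' @noRd
.write_report <- function(df, path, seed, hash) {
  con <- file(path, "w")
  writeLines(sprintf("# clonehist %s; seed=%d; config_hash=%s",
                     as.character(utils::packageVersion("clonehist")),
                     seed, hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

#' Run the analysis pipeline end to end
#'
#' Executes the configured stages in dependency order on a simulated cohort
#' (or fixtures), writing one provenance-headed TSV per stage to the output
#' directory. A stage failure halts its downstream dependents and is
#' recorded in the report; identical config and seed give byte-identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return a run report: list with `outputs` (stage -> file path),
#'   `results` (stage -> in-memory result), `errors`, `seed`, `config_hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE)
  }
  hash <- .config_hash(config[setdiff(names(config), "output_dir")])
  outputs <- list(); results <- list(); errors <- list()
  halted <- FALSE
  report <- function(df, name) {
    outputs[[name]] <<- .write_report(
      df, file.path(config$output_dir, paste0(name, ".tsv")),
      config$seed, hash)
  }
  run_stage <- function(name, fn) {
    if (halted || !(name %in% config$stages)) return(invisible(NULL))
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[name]] <<- conditionMessage(res)
      halted <<- TRUE
    } else results[[name]] <<- res
    invisible(NULL)
  }

  cohort <- NULL; panel <- NULL
  run_stage("simulate", function() {
    if (!is.null(config$cohort_config)) {
      cc <- config$cohort_config
      cc$seed <- derive_seed(config$seed, "simulate")
      cohort <<- simulate_cohort(cc)
    } else {
      stop("loading full cohorts from fixtures requires 'cohort_config'; ",
           "point individual stage functions at the fixture readers instead")
    }
    panel <<- simulate_panel(config$panel_samples, depth = cohort$config$depth,
                             seed = derive_seed(config$seed, "panel"))
    report(cohort$calls$samples, "samples")
    "simulated"
  })
  if (is.null(cohort)) {
    return(list(outputs = outputs, results = results, errors = errors,
                seed = config$seed, config_hash = hash))
  }

  run_stage("filter", function() {
    model <- fit_panel_error(panel)
    rows <- list()
    for (pid in unique(cohort$calls$samples$patient)) {
      alt <- cohort$calls$alt[[pid]]
      dep <- cohort$calls$depth[[pid]]
      tum <- !cohort$calls$samples$is_normal[
        match(colnames(alt), cohort$calls$samples$sample)]
      keep <- pileup_rescue(alt[, tum, drop = FALSE],
                            dep[, tum, drop = FALSE])
      mu_site <- rep(stats::median(model$mu), length(keep))
      pm <- structure(list(mu = mu_site, rho = model$rho,
                           pseudocounts = model$pseudocounts,
                           untestable = rep(FALSE, length(keep))),
                      class = "panel_error_model")
      calls <- betabinom_rescue(alt[keep, tum, drop = FALSE],
                                dep[keep, tum, drop = FALSE], pm,
                                alpha = config$rescue_alpha)
      rows[[pid]] <- data.frame(
        patient = pid, sites_in = nrow(alt), sites_kept = length(keep),
        present_calls = sum(calls$present))
    }
    df <- do.call(rbind, rows)
    report(df, "filter")
    df
  })

  run_stage("tree", function() {
    rows <- list()
    for (pid in unique(cohort$calls$samples$patient)) {
      v <- cohort$calls$variants[cohort$calls$variants$patient == pid, ]
      if (nrow(v) < 20) next
      samp <- cohort$calls$samples[cohort$calls$samples$patient == pid &
                                     !cohort$calls$samples$is_normal, ]
      alt <- cohort$calls$alt[[pid]][v$mut_id, samp$sample, drop = FALSE]
      dep <- cohort$calls$depth[[pid]][v$mut_id, samp$sample, drop = FALSE]
      fit <- cluster_ccf(alt, dep, purity = samp$purity,
                         cnt = matrix(v$cnt, nrow(v), nrow(samp)),
                         multiplicity = matrix(v$multiplicity, nrow(v),
                                               nrow(samp)),
                         iters = config$cluster_iters,
                         burnin = config$cluster_burnin,
                         seed = derive_seed(config$seed,
                                            paste0("tree_", pid)))
      fit <- filter_clusters(fit, config$cluster_min_fraction,
                             config$cluster_min_count)
      tree <- build_tree(fit, presence_ccf = config$presence_ccf)
      rows[[pid]] <- data.frame(
        patient = pid, n_clusters = nrow(fit$clusters),
        trunk_subs = if (is.na(tree$trunk)) NA_integer_ else
          tree$clusters$n_subs[tree$clusters$cluster == tree$trunk],
        trunk_proportion = if (is.na(tree$trunk)) NA_real_ else
          trunk_proportion(tree))
      results[["tree_objects"]][[pid]] <<- tree
    }
    df <- do.call(rbind, rows)
    report(df, "tree")
    df
  })

  run_stage("time", function() {
    rows <- list()
    for (pid in unique(cohort$calls$samples$patient)) {
      samp <- cohort$calls$samples[cohort$calls$samples$patient == pid &
                                     !cohort$calls$samples$is_normal, ]
      b <- samp$sample[1L]
      prof <- cohort$profiles[[b]]
      if (reads_per_copy(prof) < 7) next
      v <- cohort$calls$variants[cohort$calls$variants$patient == pid &
                                   cohort$calls$variants$cluster == 1L, ]
      if (!nrow(v)) next
      muts <- data.frame(chrom = v$chrom, pos = v$pos,
                         alt = cohort$calls$alt[[pid]][v$mut_id, b],
                         total = cohort$calls$depth[[pid]][v$mut_id, b])
      seg <- cohort$segments[cohort$segments$sample == b, ]
      timed <- time_segments(seg, muts, purity = prof$purity,
                             seed = derive_seed(config$seed,
                                                paste0("time_", pid)))
      est <- tryCatch(pre_dup_burden(timed), error = function(e) NULL)
      rows[[pid]] <- data.frame(
        patient = pid, wgd = classify_wgd(prof),
        genome_wide_burden = if (is.null(est)) NA_real_ else
          est$genome_wide_burden,
        divisions = if (is.null(est)) NA_integer_ else
          cell_divisions(est$genome_wide_burden)$divisions)
    }
    df <- do.call(rbind, rows)
    report(df, "time")
    df
  })

  run_stage("similarity", function() {
    rows <- list()
    trees <- results[["tree_objects"]]
    for (pid in names(trees %||% list())) {
      tree <- trees[[pid]]
      samp <- cohort$calls$samples[cohort$calls$samples$patient == pid &
                                     !cohort$calls$samples$is_normal, ]
      hist <- stats::setNames(samp$histology, samp$sample)
      if (length(unique(hist)) < 2) next
      gs <- genetic_similarity(tree, hist,
                               presence_ccf = config$presence_ccf)
      ts <- tryCatch({
        libs <- intersect(samp$sample, expr_samples(cohort$expression))
        transcriptomic_similarity(cohort$expression, libraries = libs)
      }, error = function(e) NULL)
      for (sim in list(gs, ts)) {
        if (is.null(sim)) next
        res <- tryCatch(
          label_swap_test(sim, n_perm = config$n_perm,
                          seed = derive_seed(config$seed,
                                             paste0("sim_", pid,
                                                    sim$modality))),
          error = function(e) NULL)
        if (is.null(res)) next
        rows[[paste0(pid, "_", sim$modality)]] <- data.frame(
          patient = pid, modality = sim$modality,
          observed_difference = res$observed, p = res$p, mode = res$mode)
      }
    }
    df <- do.call(rbind, rows) %||%
      data.frame(patient = character(0), modality = character(0),
                 observed_difference = numeric(0), p = numeric(0),
                 mode = character(0))
    report(df, "similarity")
    df
  })

  run_stage("dosage", function() {
    ex <- cohort$expression
    kept <- qc_libraries(ex$counts)
    tumour_libs <- intersect(kept,
                             ex$samples$sample[!ex$samples$is_normal_tubule])
    normal_libs <- intersect(kept,
                             ex$samples$sample[ex$samples$is_normal_tubule])
    blocking <- stats::setNames(ex$samples$histology, ex$samples$sample)
    de <- differential_expression(ex, tumour_libs, normal_libs,
                                  blocking = blocking)
    target <- ex$genes$gene[ex$genes$arm == config$dosage_arm]
    seg <- cohort$segments[cohort$segments$sample ==
                             cohort$calls$samples$sample[1L], ]
    seg$total_cn <- seg$major + seg$minor
    ploidy <- cohort$profiles[[cohort$calls$samples$sample[1L]]]$ploidy
    pool <- genes_near_baseline(ex$genes, seg, ploidy,
                                near_baseline = config$near_baseline)
    res <- dosage_permutation(de, target, pool, n_draws = config$n_draws,
                              seed = derive_seed(config$seed, "dosage"))
    df <- data.frame(target_arm = config$dosage_arm,
                     observed_mean_log2fc = res$observed,
                     n_target = res$n_target, n_pool = res$n_pool,
                     p = res$p)
    report(df, "dosage")
    df
  })

  run_stage("signatures", function() {
    cat96 <- toy_signature_catalogue()
    spectra <- patient_spectra(cohort$calls$variants)
    rows <- lapply(names(spectra), function(pid) {
      if (sum(spectra[[pid]]) == 0) return(NULL)
      fit <- em_attribution(spectra[[pid]], cat96)
      data.frame(patient = pid, t(fit$exposures))
    })
    df <- do.call(rbind, rows)
    report(df, "signatures")
    df
  })

  list(outputs = outputs, results = results, errors = errors,
       seed = config$seed, config_hash = hash)
}

#' Library names of an expression study
#' @param expr an [expression_study()].
#' @return character vector of library names.
#' @export
expr_samples <- function(expr) colnames(expr$counts)
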