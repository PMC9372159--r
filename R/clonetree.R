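# Clustering substitutions by cancer cell fraction (CCF) across a
# patient's biopsies with a Dirichlet-process binomial mixture, filtering
# clusters, assembling a clone tree by the pigeonhole principle, and the
# trunk-proportion statistic.

#' Cancer cell fraction of mutations
#'
#' CCF = VAF * (purity * CNt + 2 * (1 - purity)) / (purity * multiplicity).
#' Values above 1.5 are flagged (likely copy-number misspecification) and
#' capped at 1.5.
#'
#' @param alt,total read count matrices (mutations x biopsies) or vectors.
#' @param purity per-biopsy purity (recycled across mutations).
#' @param cnt local total copy number per mutation (matrix or vector).
#' @param multiplicity per-mutation multiplicity (default 1).
#' @return list with `ccf` (same shape as `alt`) and logical `flagged`.
#' @export
compute_ccf <- function(alt, total, purity, cnt, multiplicity = 1) {
  vaf <- ifelse(total > 0, alt / pmax(total, 1), NA_real_)
  if (is.matrix(vaf)) {
    purity <- matrix(purity, nrow = nrow(vaf), ncol = ncol(vaf), byrow = TRUE)
  }
  ccf <- vaf * (purity * cnt + 2 * (1 - purity)) / (purity * multiplicity)
  flagged <- !is.na(ccf) & ccf > 1.5
  ccf[flagged] <- 1.5
  list(ccf = ccf, flagged = flagged)
}

# Discrete grid prior over cluster CCFs used by the DP sampler. The grid
# spans [0, 1.25] so that a fully clonal cluster is interior.
.ccf_grid <- seq(0, 1.25, by = 0.025)

#' Dirichlet-process clustering of substitutions by CCF
#'
#' Clusters mutations across a patient's biopsies with a Dirichlet-process
#' binomial mixture: mutation i in biopsy j contributes
#' alt_ij ~ Binomial(total_ij, theta_kj * f_ij), where theta_kj is the
#' cluster's CCF in biopsy j and f_ij = m * purity / (purity * CNt +
#' 2 (1 - purity)) maps CCF to expected VAF. Cluster CCFs live on a
#' discrete grid over [0, 1.25]; assignments are resampled by a collapsed
#' Chinese-restaurant scheme and cluster CCFs by their grid posterior. The
#' returned point clustering is the recorded partition closest to the
#' posterior mean co-clustering matrix (maximum posterior similarity), ties
#' broken by the smaller cluster count.
#'
#' Only autosomal substitutions should be supplied (filter beforehand);
#' biopsies should have an average of >= 5 reads per chromosome copy.
#'
#' @param alt,total mutations x biopsies count matrices.
#' @param purity per-biopsy purity vector.
#' @param cnt total copy number per mutation per biopsy (matrix, or scalar
#'   recycled); default 2.
#' @param multiplicity per-mutation multiplicity (vector or matrix);
#'   default 1.
#' @param iters,burnin Gibbs sweeps and burn-in; defaults 1000 and 200
#'   (use 3000/1000 for <= 5 biopsies when runtime allows).
#' @param concentration Dirichlet-process concentration parameter alpha.
#' @param seed integer seed; the sampler is deterministic given it.
#' @return an object of class `ccf_clusters`: data.frame `clusters`
#'   (cluster, n_subs, one `ccf_<biopsy>` column per biopsy), integer
#'   `assignment` per mutation (`NA` for mutations with zero depth
#'   everywhere), and the `ccf` matrix used.
#' @export
cluster_ccf <- function(alt, total, purity, cnt = 2, multiplicity = 1,
                        iters = 1000, burnin = 200, concentration = 1.0,
                        seed = NULL) {
  stopifnot(is.matrix(alt), all(dim(alt) == dim(total)),
            length(purity) == ncol(alt), iters > burnin)
  n <- nrow(alt); J <- ncol(alt)
  if (n == 0L) {
    clusters <- data.frame(cluster = integer(0), n_subs = integer(0))
    return(structure(list(clusters = clusters, assignment = integer(0),
                          ccf = alt), class = "ccf_clusters"))
  }
  cnt_m <- if (is.matrix(cnt)) cnt else matrix(cnt, n, J)
  mult_m <- if (is.matrix(multiplicity)) multiplicity else
    matrix(multiplicity, n, J)
  pur_m <- matrix(purity, n, J, byrow = TRUE)
  f <- pmin(mult_m * pur_m / (pur_m * cnt_m + 2 * (1 - pur_m)), 1)
  usable <- rowSums(total) > 0
  idx <- which(usable)
  if (!length(idx)) {
    clusters <- data.frame(cluster = integer(0), n_subs = integer(0))
    return(structure(list(clusters = clusters,
                          assignment = rep(NA_integer_, n), ccf = alt * NA),
                     class = "ccf_clusters"))
  }
  grid <- .ccf_grid
  G <- length(grid)
  # Pre-compute per-mutation, per-biopsy log-likelihood across the grid:
  # ll_grid[[j]] is n x G.
  ll_grid <- lapply(seq_len(J), function(j) {
    p <- outer(f[, j], grid)          # n x G success probabilities
    p <- pmin(p, 1)
    stats::dbinom(alt[, j], total[, j], p, log = TRUE)
  })
  # loglik of mutation i under a cluster with grid indices g (length J)
  mut_ll <- function(i, gidx) {
    s <- 0
    for (j in seq_len(J)) s <- s + ll_grid[[j]][i, gidx[j]]
    s
  }
  # marginal loglik of mutation i under a fresh cluster (uniform grid prior,
  # biopsies independent)
  new_ll <- vapply(seq_len(n), function(i) {
    s <- 0
    for (j in seq_len(J)) {
      m <- max(ll_grid[[j]][i, ])
      s <- s + m + log(mean(exp(ll_grid[[j]][i, ] - m)))
    }
    s
  }, numeric(1))

  with_seed(seed, {
    z <- rep(1L, n)                    # cluster assignment
    theta_g <- matrix(which.min(abs(grid - 1)), nrow = 1L, ncol = J)
    sample_theta <- function(members) {
      vapply(seq_len(J), function(j) {
        lp <- colSums(ll_grid[[j]][members, , drop = FALSE])
        lp <- lp - max(lp)
        sample.int(G, 1L, prob = exp(lp))
      }, integer(1))
    }
    recorded <- vector("list", iters - burnin)
    for (sweep in seq_len(iters)) {
      for (i in idx) {
        zi <- z[i]
        z[i] <- 0L
        sizes <- tabulate(z[idx], nbins = max(z, zi))
        keep <- which(sizes > 0L)
        if (!length(keep)) {
          z[i] <- 1L
          theta_g <- matrix(sample_theta(i), nrow = 1L)
          next
        }
        lw <- vapply(keep, function(k)
          log(sizes[k]) + mut_ll(i, theta_g[k, ]), numeric(1))
        lw <- c(lw, log(concentration) + new_ll[i])
        lw <- lw - max(lw)
        pick <- sample.int(length(lw), 1L, prob = exp(lw))
        if (pick <= length(keep)) {
          z[i] <- keep[pick]
        } else {
          k_new <- if (length(keep) == nrow(theta_g)) nrow(theta_g) + 1L else
            setdiff(seq_len(nrow(theta_g)), keep)[1L]
          if (k_new > nrow(theta_g)) {
            theta_g <- rbind(theta_g, sample_theta(i))
          } else theta_g[k_new, ] <- sample_theta(i)
          z[i] <- k_new
        }
      }
      # relabel to compact ids and resample cluster CCFs
      labs <- sort(unique(z[idx]))
      z[idx] <- match(z[idx], labs)
      theta_new <- matrix(0L, length(labs), J)
      for (k in seq_along(labs)) {
        theta_new[k, ] <- sample_theta(idx[z[idx] == k])
      }
      theta_g <- theta_new
      if (sweep > burnin) recorded[[sweep - burnin]] <- z[idx]
    }
    # posterior mean co-clustering and maximum-posterior-similarity partition
    R <- length(recorded)
    m_use <- length(idx)
    co <- matrix(0, m_use, m_use)
    for (r in seq_len(R)) {
      zz <- recorded[[r]]
      co <- co + outer(zz, zz, "==")
    }
    co <- co / R
    score <- vapply(seq_len(R), function(r) {
      zz <- recorded[[r]]
      sum((outer(zz, zz, "==") - co)^2)
    }, numeric(1))
    nclus <- vapply(recorded, function(zz) length(unique(zz)), numeric(1))
    best <- order(score, nclus)[1L]
    z_best <- recorded[[best]]

    ccf_obs <- compute_ccf(alt, total, purity, cnt_m, mult_m)$ccf
    assignment <- rep(NA_integer_, n)
    assignment[idx] <- z_best
    labs <- sort(unique(z_best))
    clusters <- data.frame(cluster = seq_along(labs),
                           n_subs = as.integer(tabulate(match(z_best, labs))))
    ccf_cols <- vapply(seq_len(J), function(j) {
      vapply(labs, function(k)
        stats::median(ccf_obs[idx[z_best == k], j], na.rm = TRUE), numeric(1))
    }, numeric(length(labs)))
    ccf_cols <- matrix(ccf_cols, nrow = length(labs))
    colnames(ccf_cols) <- paste0("ccf_",
                                 colnames(alt) %||% seq_len(J))
    clusters <- cbind(clusters, as.data.frame(ccf_cols))
    assignment[idx] <- match(z_best, labs)
    structure(list(clusters = clusters, assignment = assignment,
                   ccf = ccf_obs), class = "ccf_clusters")
  })
}

#' @export
print.ccf_clusters <- function(x, ...) {
  cat(sprintf("ccf_clusters: %d clusters over %d mutations\n",
              nrow(x$clusters), length(x$assignment)))
  print(x$clusters)
  invisible(x)
}

#' Filter mutation clusters
#'
#' Removes clusters accounting for less than `min_fraction` of the
#' patient's substitutions or holding fewer than `min_count` substitutions.
#' Mutations of removed clusters become unassigned.
#'
#' @param fit a `ccf_clusters` object.
#' @param min_fraction minimum fraction of total substitutions; default 0.01.
#' @param min_count minimum substitutions per cluster; default 20.
#' @return the filtered `ccf_clusters` object; removed cluster ids in
#'   attribute `removed`.
#' @export
filter_clusters <- function(fit, min_fraction = 0.01, min_count = 20) {
  stopifnot(inherits(fit, "ccf_clusters"))
  total <- sum(fit$clusters$n_subs)
  bad <- fit$clusters$n_subs < min_count |
    fit$clusters$n_subs < min_fraction * total
  removed <- fit$clusters$cluster[bad]
  fit$clusters <- fit$clusters[!bad, , drop = FALSE]
  fit$assignment[fit$assignment %in% removed] <- NA_integer_
  attr(fit, "removed") <- removed
  fit
}

#' Assemble a clone tree from mutation clusters
#'
#' The trunk is the cluster present (CCF strictly > `presence_ccf`) in all
#' biopsies with the maximal mean CCF. Every other cluster is nested under
#' the dominating cluster (CCF >= child CCF - `tolerance` in every biopsy)
#' with the smallest total CCF, implementing the pigeonhole ordering.
#' Clusters violating the pigeonhole constraint against every candidate
#' parent by more than `violation_ccf`, while holding under 5% of the
#' trunk's mutations, are flagged as tree-violating (candidates for
#' removal). When a `gcnis` / `invasive` biopsy split is supplied, clusters
#' present in both compartments are merged into the trunk (shared in-situ /
#' invasive mutations are truncal by definition).
#'
#' @param fit a `ccf_clusters` object (typically after [filter_clusters()]).
#' @param presence_ccf presence threshold; a cluster is present in a biopsy
#'   when its CCF is strictly greater than this (default 0.1).
#' @param tolerance pigeonhole slack per biopsy; default 0.05.
#' @param violation_ccf residual above which a small cluster is flagged as
#'   violating the tree; default 0.1.
#' @param gcnis_biopsies optional character vector naming in-situ (GCNIS)
#'   biopsies; the rest are treated as invasive.
#' @return an object of class `clone_tree`: data.frame `clusters` with
#'   `parent` (NA for the trunk) plus the input CCF columns, `trunk` id
#'   (NA when no cluster pervades all biopsies, in which case the result is
#'   a forest and a diagnostic is attached), and `violations`.
#' @export
build_tree <- function(fit, presence_ccf = 0.1, tolerance = 0.05,
                       violation_ccf = 0.1, gcnis_biopsies = NULL) {
  stopifnot(inherits(fit, "ccf_clusters"))
  cl <- fit$clusters
  if (nrow(cl) == 0L) stop("no clusters to build a tree from")
  ccf_cols <- grep("^ccf_", names(cl), value = TRUE)
  ccf <- as.matrix(cl[, ccf_cols, drop = FALSE])
  present <- ccf > presence_ccf
  in_all <- rowSums(present) == ncol(ccf)
  trunk <- if (any(in_all)) {
    cand <- which(in_all)
    cand[which.max(rowMeans(ccf[cand, , drop = FALSE]))]
  } else NA_integer_

  if (!is.null(gcnis_biopsies) && !is.na(trunk)) {
    biopsy <- sub("^ccf_", "", ccf_cols)
    is_gcnis <- biopsy %in% gcnis_biopsies
    if (any(is_gcnis) && any(!is_gcnis)) {
      shared <- which(rowSums(present[, is_gcnis, drop = FALSE]) > 0 &
                        rowSums(present[, !is_gcnis, drop = FALSE]) > 0)
      shared <- setdiff(shared, trunk)
      if (length(shared)) {
        trunk_id <- cl$cluster[trunk]
        cl$n_subs[trunk] <- cl$n_subs[trunk] + sum(cl$n_subs[shared])
        cl <- cl[-shared, , drop = FALSE]
        ccf <- ccf[-shared, , drop = FALSE]
        present <- present[-shared, , drop = FALSE]
        trunk <- which(cl$cluster == trunk_id)
      }
    }
  }

  n_k <- nrow(cl)
  parent <- rep(NA_integer_, n_k)
  violation <- rep(FALSE, n_k)
  if (!is.na(trunk)) {
    # rank clusters by total CCF (trunk first); a parent must rank strictly
    # higher than its child, which guarantees an acyclic tree even when
    # sibling clusters have identical CCFs
    rank_order <- order(-rowSums(ccf))
    rank_order <- c(trunk, setdiff(rank_order, trunk))
    rank_pos <- match(seq_len(n_k), rank_order)
    for (k in seq_len(n_k)) {
      if (k == trunk) next
      cand <- Filter(function(p) {
        rank_pos[p] < rank_pos[k] && all(ccf[p, ] >= ccf[k, ] - tolerance)
      }, seq_len(n_k))
      if (!length(cand)) {
        # no dominator at the set tolerance: attach under the trunk but
        # flag when the residual is material and the cluster is small
        parent[k] <- trunk
        resid <- max(ccf[k, ] - ccf[trunk, ])
        if (resid > violation_ccf &&
            cl$n_subs[k] < 0.05 * cl$n_subs[trunk]) violation[k] <- TRUE
      } else {
        cand <- unlist(cand)
        parent[k] <- cand[which.min(rowSums(ccf[cand, , drop = FALSE]))]
      }
    }
  }
  cl$parent <- ifelse(is.na(parent), NA_integer_, cl$cluster[parent])
  out <- structure(list(clusters = cl,
                        trunk = if (is.na(trunk)) NA_integer_ else
                          cl$cluster[trunk],
                        presence_ccf = presence_ccf,
                        violations = cl$cluster[violation]),
                   class = "clone_tree")
  if (is.na(trunk)) {
    attr(out, "diagnostic") <-
      "no cluster is present in every biopsy; result is a forest"
  }
  out
}

#' @export
print.clone_tree <- function(x, ...) {
  if (is.na(x$trunk)) {
    cat("clone_tree (forest): no trunk —", attr(x, "diagnostic"), "\n")
  } else {
    cat(sprintf("clone_tree: %d clusters, trunk = cluster %d (%d subs)\n",
                nrow(x$clusters), x$trunk,
                x$clusters$n_subs[x$clusters$cluster == x$trunk]))
  }
  print(x$clusters)
  invisible(x)
}

#' Proportion of substitutions in the phylogenetic trunk
#'
#' trunk / (trunk + mean tip distance), where the mean tip distance is the
#' summed mutation distance from the trunk to each branch tip divided by
#' the number of tips. Internal branches shared by several tips are counted
#' once per tip passing through them (double-counting), which normalises
#' all subclonal branch lengths equally. A tree with no subclonal branches
#' has trunk proportion 1.
#'
#' @param tree a `clone_tree` with a trunk.
#' @return the trunk proportion in (0, 1].
#' @export
trunk_proportion <- function(tree) {
  stopifnot(inherits(tree, "clone_tree"))
  if (is.na(tree$trunk)) stop("tree is a forest (no trunk); proportion undefined")
  cl <- tree$clusters
  n_trunk <- cl$n_subs[cl$cluster == tree$trunk]
  non_trunk <- cl$cluster[cl$cluster != tree$trunk]
  if (!length(non_trunk)) return(1.0)
  tips <- setdiff(non_trunk, cl$parent[!is.na(cl$parent)])
  dist_to_trunk <- function(k) {
    d <- 0; steps <- 0L
    while (!is.na(k) && k != tree$trunk) {
      d <- d + cl$n_subs[cl$cluster == k]
      k <- cl$parent[cl$cluster == k]
      steps <- steps + 1L
      if (steps > nrow(cl)) stop("cycle in parent links; tree is malformed")
    }
    d
  }
  dists <- vapply(tips, dist_to_trunk, numeric(1))
  n_trunk / (n_trunk + sum(dists) / length(tips))
}

#' Export a clone tree as Newick
#'
#' Branch lengths are substitution counts; the trunk is the root edge.
#'
#' @param tree a `clone_tree` with a trunk.
#' @return a Newick string.
#' @export
tree_newick <- function(tree) {
  stopifnot(inherits(tree, "clone_tree"))
  if (is.na(tree$trunk)) stop("forest cannot be serialised as a single Newick tree")
  cl <- tree$clusters
  rec <- function(k) {
    kids <- cl$cluster[!is.na(cl$parent) & cl$parent == k]
    len <- cl$n_subs[cl$cluster == k]
    if (!length(kids)) return(sprintf("c%d:%d", k, len))
    sprintf("(%s)c%d:%d", paste(vapply(kids, rec, character(1)),
                                collapse = ","), k, len)
  }
  paste0(rec(tree$trunk), ";")
}
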