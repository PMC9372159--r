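# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' that seeded package functions do not perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

#' Derive a reproducible sub-seed from a master seed and a stage name
#'
#' Hashes the stage name (FNV-1a over UTF-8 bytes) into the master seed so
#' each pipeline stage gets its own stream yet remains individually
#' reproducible. Result is kept below 2^31.
#' @param seed integer master seed.
#' @param name character stage name.
#' @return integer sub-seed.
#' @export
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 2166136261
  for (b in utf8ToInt(name)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer((as.numeric(seed) + h) %% .Machine$integer.max)
}

#' @noRd
assert_prob <- function(x, name, open_left = FALSE, open_right = FALSE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!all(is.finite(x) & lo_ok & hi_ok)) {
    stop(sprintf("'%s' must lie in %s0, 1%s", name,
                 if (open_left) "(" else "[", if (open_right) ")" else "]"),
         call. = FALSE)
  }
  invisible(x)
}

# Length-weighted interval bookkeeping: total bases of `x` (two-column
# matrix of 0-based half-open [start, end)) not covered by `mask`.
# Intervals are merged before subtraction; both inputs may be empty.
#' @noRd
interval_uncovered <- function(x, mask) {
  merge_iv <- function(m) {
    if (is.null(m) || nrow(m) == 0L) return(matrix(numeric(0), ncol = 2L))
    m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
    out <- m[1L, , drop = FALSE]
    if (nrow(m) > 1L) for (i in 2L:nrow(m)) {
      k <- nrow(out)
      if (m[i, 1L] <= out[k, 2L]) {
        out[k, 2L] <- max(out[k, 2L], m[i, 2L])
      } else out <- rbind(out, m[i, , drop = FALSE])
    }
    out
  }
  x <- merge_iv(x); mask <- merge_iv(mask)
  if (nrow(x) == 0L) return(0)
  total <- sum(x[, 2L] - x[, 1L])
  if (nrow(mask) == 0L) return(total)
  overlap <- 0
  for (i in seq_len(nrow(x))) {
    lo <- pmax(x[i, 1L], mask[, 1L])
    hi <- pmin(x[i, 2L], mask[, 2L])
    overlap <- overlap + sum(pmax(0, hi - lo))
  }
  total - overlap
}
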