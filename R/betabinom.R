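# Beta-binomial density and tail used by the panel error model.
#
# Parameterised by mean mu and overdispersion rho (the intra-class
# correlation), with shape parameters
#   alpha = mu * (1 - rho) / rho,  beta = (1 - mu) * (1 - rho) / rho,
# so rho -> 0 recovers the plain binomial.

#' Beta-binomial density
#'
#' @param x number of successes (vectorised).
#' @param size number of trials.
#' @param mu mean success fraction in (0, 1).
#' @param rho overdispersion (intra-class correlation) in (0, 1).
#' @param log return log density?
#' @return density values.
#' @export
dbetabinom <- function(x, size, mu, rho, log = FALSE) {
  stopifnot(all(mu > 0 & mu < 1), all(rho > 0 & rho < 1))
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  ld <- lchoose(size, x) + lbeta(x + a, size - x + b) - lbeta(a, b)
  ld[x < 0 | x > size] <- -Inf
  if (log) ld else exp(ld)
}

#' Beta-binomial upper tail probability P[X >= x]
#'
#' @inheritParams dbetabinom
#' @return tail probabilities; x <= 0 gives 1.
#' @export
pbetabinom_upper <- function(x, size, mu, rho) {
  n <- max(length(x), length(size), length(mu), length(rho))
  x <- rep_len(x, n); size <- rep_len(size, n)
  mu <- rep_len(mu, n); rho <- rep_len(rho, n)
  vapply(seq_len(n), function(i) {
    if (x[i] <= 0) return(1)
    if (x[i] > size[i]) return(0)
    ks <- x[i]:size[i]
    sum(dbetabinom(ks, size[i], mu[i], rho[i]))
  }, numeric(1))
}

#' Draw beta-binomial counts
#'
#' @inheritParams dbetabinom
#' @param n number of draws.
#' @return integer vector of counts.
#' @export
rbetabinom <- function(n, size, mu, rho) {
  if (any(rho <= 0)) stop("rho must be > 0; use rbinom for the binomial limit")
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  p <- stats::rbeta(n, a, b)
  stats::rbinom(n, size, p)
}
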