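# Discrete power-law fitting and plausibility -------------------------------
#
# Scale-free topology is assessed by fitting a discrete power law
# P(k) ~ k^(-alpha) for k >= xmin to the degree sequence: alpha by maximum
# likelihood at each candidate xmin, xmin by minimizing the Kolmogorov-
# Smirnov distance between the empirical tail and the fitted model, and a
# semi-parametric bootstrap goodness-of-fit p-value (refitting each
# replicate).  The power law is considered plausible when p > 0.1.

# Hurwitz zeta(alpha, xmin), truncated sum plus Euler-Maclaurin tail.
.hzeta <- function(alpha, xmin, nterms = 2000L) {
  k <- seq(xmin, xmin + nterms - 1L)
  tail_start <- xmin + nterms - 0.5
  sum(k^(-alpha)) + tail_start^(1 - alpha) / (alpha - 1)
}

.pl_loglik <- function(alpha, xtail, xmin, sumlog) {
  -length(xtail) * log(.hzeta(alpha, xmin)) - alpha * sumlog
}

# exact maximum-likelihood alpha at a given xmin
.pl_mle_exact <- function(x, xmin) {
  xtail <- x[x >= xmin]
  sumlog <- sum(log(xtail))
  optimize(function(a) -.pl_loglik(a, xtail, xmin, sumlog),
           interval = c(1.01, 25))$minimum
}

.pl_fit_at <- function(x, xmin) {
  xtail <- x[x >= xmin]
  # closed-form approximation to the discrete MLE as the starting point,
  # refined by a short exact likelihood optimization
  a0 <- 1 + length(xtail) / sum(log(xtail / (xmin - 0.5)))
  a0 <- min(max(a0, 1.05), 24)
  sumlog <- sum(log(xtail))
  alpha <- optimize(function(a) -.pl_loglik(a, xtail, xmin, sumlog),
                    interval = c(max(1.01, a0 - 1), min(25, a0 + 1)),
                    tol = 1e-3)$minimum
  ks <- .pl_ks(xtail, alpha, xmin)
  list(alpha = alpha, xmin = xmin, ks = ks, ntail = length(xtail))
}

.pl_ks <- function(xtail, alpha, xmin) {
  z <- .hzeta(alpha, xmin)
  grid <- seq(xmin, max(xtail))
  cdf_fit <- cumsum(grid^(-alpha) / z)
  counts <- tabulate(xtail - xmin + 1L, nbins = length(grid))
  cdf_emp <- cumsum(counts) / length(xtail)
  max(abs(cdf_emp - cdf_fit))
}

.pl_fit <- function(x, max_candidates = 25L) {
  cands <- sort(unique(x))
  cands <- cands[cands <= sort(x, decreasing = TRUE)[min(length(x), 10L)]]
  if (length(cands) > max_candidates)
    cands <- unique(round(quantile(cands, seq(0, 1, length.out = max_candidates),
                                   type = 1)))
  fits <- lapply(cands, function(xm) .pl_fit_at(x, xm))
  fits[[which.min(vapply(fits, `[[`, numeric(1), "ks"))]]
}

# inverse-CDF sampler for the fitted discrete power law
.pl_sample <- function(n, alpha, xmin) {
  top <- xmin + 5000L
  grid <- seq(xmin, top)
  cdf <- cumsum(grid^(-alpha))
  # normalize by the truncated total so the cdf is exactly monotone with 1
  # as its final value (the mass beyond `top` is negligible at alpha > 1)
  cdf <- cdf / cdf[length(cdf)]
  grid[findInterval(runif(n), cdf) + 1L]
}

#' Plausibility of a discrete power law for a degree sequence
#'
#' Fits alpha (maximum likelihood) and xmin (KS-minimizing), then assesses
#' goodness of fit with a Clauset-style semi-parametric bootstrap: each
#' replicate resamples values below xmin from the data and values at or
#' above xmin from the fitted power law, is refitted, and contributes its KS
#' distance to the null distribution.  `plausible` is `TRUE` when
#' `bootstrap_p > 0.1`.
#'
#' @param degrees positive integer degree values (at least 10; zero degrees
#'   are dropped).
#' @param n_bootstrap bootstrap replicates.
#' @param seed optional integer seed.
#' @return list with `alpha`, `xmin`, `ks_statistic`, `bootstrap_p`,
#'   `plausible`, `n_bootstrap`, `n_tail`, `seed`.
#' @export
powerlaw_plausibility <- function(degrees, n_bootstrap = 1000L, seed = NULL) {
  x <- as.integer(degrees)
  x <- x[x > 0L]
  if (length(x) < 10L) stop("need at least 10 positive degrees")
  if (length(unique(x)) == 1L)
    stop("degenerate degree sequence: all degrees equal")
  if (!is.null(seed)) set.seed(seed)
  fit <- .pl_fit(x)
  n <- length(x)
  below <- x[x < fit$xmin]
  ptail <- fit$ntail / n
  ks_null <- numeric(n_bootstrap)
  for (b in seq_len(n_bootstrap)) {
    from_tail <- if (length(below)) rbinom(1L, n, ptail) else n
    xb <- c(if (from_tail > 0L) .pl_sample(from_tail, fit$alpha, fit$xmin),
            if (n - from_tail > 0L) sample(below, n - from_tail, replace = TRUE))
    ks_null[b] <- .pl_fit(xb)$ks
  }
  p <- mean(ks_null >= fit$ks)
  list(alpha = fit$alpha, xmin = fit$xmin, ks_statistic = fit$ks,
       bootstrap_p = p, plausible = p > 0.1,
       n_bootstrap = n_bootstrap, n_tail = fit$ntail,
       seed = if (is.null(seed)) NA else seed)
}

#' Sample from a discrete power law (for simulation studies)
#'
#' @param n number of draws.
#' @param alpha scaling exponent (> 1).
#' @param xmin minimum value.
#' @param seed optional integer seed.
#' @export
rpowerlaw <- function(n, alpha, xmin = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .pl_sample(n, alpha, xmin)
}
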