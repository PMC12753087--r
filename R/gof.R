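#' Kolmogorov-Smirnov goodness of fit to the IER model
#'
#' One-sample K-S statistic \eqn{D_n = \sup_x |F_n(x) - F(x; \theta,
#' \lambda)|}, computed by direct enumeration of the ECDF jumps, with its
#' p-value from the asymptotic Kolmogorov series
#' \eqn{2\sum_{k\ge1} (-1)^{k-1} e^{-2 k^2 n D_n^2}}.  The supplied
#' parameters are treated as known — fitted values are simply plugged in,
#' with no correction for estimation — which is the convention under which
#' published fit checks of this kind are reproducible.
#'
#' @param data positive numeric vector (complete sample).
#' @inheritParams ier
#' @return list with `statistic` and `p.value`.
#' @examples
#' ks_gof(arthritis_relief(), theta = 55.334, lambda = 3.8129)
#' @export
ks_gof <- function(data, theta, lambda) {
  check_x(data, "data"); check_params(theta, lambda)
  n <- length(data)
  x <- sort(data)
  Fx <- pier(x, theta, lambda)
  D <- max(pmax(seq_len(n) / n - Fx, Fx - (seq_len(n) - 1) / n))
  z <- sqrt(n) * D
  k <- seq_len(100)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * z^2))
  list(statistic = D, p.value = min(max(p, 0), 1))
}

#' Empirical reliability function
#'
#' The right-continuous step function \eqn{x \mapsto} proportion of
#' observations exceeding \eqn{x}, i.e. \eqn{1 - F_n(x)}.
#'
#' @param data positive numeric vector.
#' @return a function of class `stepfun`; `knots()` recovers the jump
#'   locations for plotting against a fitted [ier_reliability] curve.
#' @export
empirical_reliability <- function(data) {
  check_x(data, "data")
  Fn <- stats::ecdf(data)
  f <- function(x) 1 - Fn(x)
  attr(f, "knots") <- stats::knots(Fn)
  class(f) <- c("empirical_reliability", "function")
  f
}

#' Log-likelihood surface on a parameter grid
#'
#' Dense evaluation of the PHT-ICS log-likelihood over a
#' `theta_range` x `lambda_range` grid, for contour plotting and for
#' verifying that the fitted maximum is an interior, unique mode.
#'
#' @inheritParams ier_loglik
#' @param theta_range,lambda_range length-2 positive ranges.
#' @param resolution number of grid points per axis.
#' @return list with `theta`, `lambda` (grid axes) and `loglik`
#'   (resolution x resolution matrix).
#' @export
loglik_grid <- function(sample, theta_range, lambda_range, resolution = 50) {
  th <- seq(theta_range[1], theta_range[2], length.out = resolution)
  la <- seq(lambda_range[1], lambda_range[2], length.out = resolution)
  z <- outer(th, la, Vectorize(function(a, b) ier_loglik(a, b, sample)))
  list(theta = th, lambda = la, loglik = z)
}
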