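#' @keywords internal
"_PACKAGE"

## Stable evaluation of log(1 - exp(-y)) for y > 0.  Every likelihood-type
## expression in this package involves log(1 - exp(-lambda/x^2)) raised to
## large powers, so catastrophic cancellation here would propagate everywhere.
log1mexp <- function(y) {
  out <- y
  small <- y <= log(2)
  out[small] <- log(-expm1(-y[small]))
  out[!small] <- log1p(-exp(-y[!small]))
  out
}

check_params <- function(theta, lambda) {
  if (!is.numeric(theta) || !is.numeric(lambda) ||
      any(!is.finite(theta)) || any(!is.finite(lambda)) ||
      any(theta <= 0) || any(lambda <= 0)) {
    stop("'theta' and 'lambda' must be finite and strictly positive", call. = FALSE)
  }
  invisible(TRUE)
}

check_x <- function(x, what = "x") {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be finite and strictly positive", what), call. = FALSE)
  }
  invisible(TRUE)
}

#' The inverted exponentiated Rayleigh distribution
#'
#' Density, distribution function, reliability (survival), hazard rate,
#' cumulative hazard, quantile function and random generation for the
#' inverted exponentiated Rayleigh (IER) distribution with shape `theta`
#' and scale `lambda`.
#'
#' The IER distribution has density
#' \deqn{f(x) = 2\theta\lambda x^{-3} [1 - e^{-\lambda x^{-2}}]^{\theta-1}
#'   e^{-\lambda x^{-2}}, \quad x > 0,}
#' distribution function \eqn{F(x) = 1 - [1 - e^{-\lambda x^{-2}}]^\theta},
#' reliability \eqn{R(x) = [1 - e^{-\lambda x^{-2}}]^\theta}, hazard rate
#' \eqn{H(x) = 2\theta\lambda x^{-3} e^{-\lambda x^{-2}} /
#'   (1 - e^{-\lambda x^{-2}})} and cumulative hazard
#' \eqn{-\theta \log(1 - e^{-\lambda x^{-2}})}.  It is the distribution of
#' the reciprocal of an exponentiated Rayleigh variate and accommodates
#' decreasing and upside-down-bathtub hazard shapes, which makes it a useful
#' lifetime model for relief/remission times in medical follow-up data.
#'
#' All functions validate their arguments and signal an error on values
#' outside the support or non-positive parameters (rather than returning
#' `NaN`): downstream optimizers work on the log-parameter scale, so an
#' invalid value always indicates a programming error.  Internally the
#' term \eqn{\log(1 - e^{-\lambda x^{-2}})} is evaluated through
#' `expm1`/`log1p` so that the functions remain accurate for
#' \eqn{\lambda x^{-2}} up to several hundred.
#'
#' @param x,q vector of positive quantiles (lifetimes).
#' @param p vector of probabilities in (0, 1).
#' @param n number of draws.
#' @param theta positive shape parameter.
#' @param lambda positive scale parameter.
#' @param log,log.p logical; if `TRUE`, probabilities/densities are returned
#'   on the log scale.
#' @param lower.tail logical; if `TRUE` (default) probabilities are
#'   \eqn{P(X \le x)}.
#' @param seed optional integer seed applied locally for reproducible draws.
#'
#' @return `dier` the density, `pier` the distribution function, `qier` the
#'   quantile function, `rier` random deviates; `ier_reliability`,
#'   `ier_hazard` and `ier_cumhaz` the reliability, hazard rate and
#'   cumulative hazard functions.
#'
#' @examples
#' ier_reliability(0.5, theta = 0.4, lambda = 0.8)   # 0.9834913
#' ier_hazard(0.5, theta = 0.4, lambda = 0.8)        # 0.2175712
#' pier(qier(0.5, 2, 1), 2, 1)
#' @name ier
NULL

#' @rdname ier
#' @export
dier <- function(x, theta, lambda, log = FALSE) {
  check_x(x); check_params(theta, lambda)
  y <- lambda / x^2
  logf <- log(2) + log(theta) + log(lambda) - 3 * log(x) +
    (theta - 1) * log1mexp(y) - y
  if (log) logf else exp(logf)
}

#' @rdname ier
#' @export
pier <- function(q, theta, lambda, lower.tail = TRUE, log.p = FALSE) {
  check_x(q, "q"); check_params(theta, lambda)
  logR <- theta * log1mexp(lambda / q^2)
  if (!lower.tail) {
    return(if (log.p) logR else exp(logR))
  }
  p <- -expm1(logR)
  if (log.p) log(p) else p
}

#' @rdname ier
#' @export
ier_reliability <- function(x, theta, lambda) {
  pier(x, theta, lambda, lower.tail = FALSE)
}

#' @rdname ier
#' @export
ier_hazard <- function(x, theta, lambda) {
  check_x(x); check_params(theta, lambda)
  y <- lambda / x^2
  exp(log(2) + log(theta) + log(lambda) - 3 * log(x) - y - log1mexp(y))
}

#' @rdname ier
#' @export
ier_cumhaz <- function(x, theta, lambda) {
  check_x(x); check_params(theta, lambda)
  -theta * log1mexp(lambda / x^2)
}

#' @rdname ier
#' @export
qier <- function(p, theta, lambda) {
  check_params(theta, lambda)
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("'p' must lie strictly inside (0, 1)", call. = FALSE)
  }
  ## F(x) = p  <=>  x = sqrt(-lambda / log(1 - (1-p)^(1/theta)))
  ## computed as log(-expm1(log1p(-p)/theta)) for accuracy near both tails.
  loginner <- log(-expm1(log1p(-p) / theta))
  sqrt(-lambda / loginner)
}

#' @rdname ier
#' @export
rier <- function(n, theta, lambda, seed = NULL) {
  check_params(theta, lambda)
  if (length(n) != 1L || !is.finite(n) || n < 1) stop("'n' must be a positive count", call. = FALSE)
  local_seed(seed)
  qier(stats::runif(n), theta, lambda)
}

## Set the RNG seed only for the enclosing call, restoring the caller's
## stream afterwards so that simulation helpers do not clobber it.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv(), inherits = FALSE)
  do.call(on.exit,
          list(bquote(assign(".Random.seed", .(old), globalenv())), add = TRUE),
          envir = envir)
  set.seed(as.integer(seed))
  invisible(NULL)
}
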