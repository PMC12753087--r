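## Shared sample unpacking for the likelihood-type objectives.  Works for a
## phtics_sample; a complete (uncensored) numeric vector is promoted to the
## trivial plan with no removals.
unpack_sample <- function(s) {
  if (is.numeric(s)) {
    n <- length(s)
    s <- as_phtics(sort(s), censoring_plan(n, n, integer(n) * 0L,
                                           threshold = max(s) * 2))
  }
  stopifnot(inherits(s, "phtics_sample"))
  list(x = s$times, r = s$r, R = as.numeric(s$removals_applied),
       C = s$C, R_T = as.numeric(s$R_T))
}

#' Log-likelihood, score and observed information under PHT-ICS
#'
#' The log-likelihood of an IER sample under progressive hybrid Type-I
#' censoring is
#' \deqn{\ell = \sum_{i=1}^r \log f(x_i) + \theta \sum_{i=1}^r R_i
#'   \log(1 - e^{-\lambda x_i^{-2}}) + \theta R_T \log(1 - e^{-\lambda C^{-2}}),}
#' i.e. each observed failure contributes its density and each withdrawn unit
#' a survival factor at its withdrawal time (the termination point `C` for
#' the `R_T` units removed when the time limit fires).  For a complete sample
#' this is exactly the iid log-likelihood.  `ier_score` returns the analytic
#' gradient in \eqn{(\theta, \lambda)} and `ier_observed_info` the negated
#' analytic Hessian (observed Fisher information), whose inverse is the
#' asymptotic covariance of the MLEs.
#'
#' @param theta,lambda positive IER parameters.
#' @param sample a `phtics_sample`, or a bare numeric vector which is treated
#'   as a complete sample.
#' @return `ier_loglik` a scalar; `ier_score` a length-2 vector
#'   (`dtheta`, `dlambda`); `ier_observed_info` a 2x2 matrix.
#' @seealso [fit_ier]
#' @export
ier_loglik <- function(theta, lambda, sample) {
  check_params(theta, lambda)
  u <- unpack_sample(sample)
  lw <- log1mexp(lambda / u$x^2)
  lwC <- log1mexp(lambda / u$C^2)
  sum(log(2) + log(theta) + log(lambda) - 3 * log(u$x) - lambda / u$x^2 +
        (theta - 1) * lw) +
    theta * sum(u$R * lw) + theta * u$R_T * lwC
}

#' @rdname ier_loglik
#' @export
ier_score <- function(theta, lambda, sample) {
  check_params(theta, lambda)
  u <- unpack_sample(sample)
  xi2 <- 1 / u$x^2; Ci2 <- 1 / u$C^2
  lw <- log1mexp(lambda * xi2); lwC <- log1mexp(lambda * Ci2)
  ## e^{-y}/(1-e^{-y}) evaluated as exp(-y - log(1-e^{-y}))
  g <- exp(-lambda * xi2 - lw); gC <- exp(-lambda * Ci2 - lwC)
  dtheta <- u$r / theta + sum((1 + u$R) * lw) + u$R_T * lwC
  dlambda <- u$r / lambda - sum(xi2) +
    sum((theta * (1 + u$R) - 1) * xi2 * g) + theta * u$R_T * Ci2 * gC
  c(dtheta = dtheta, dlambda = dlambda)
}

#' @rdname ier_loglik
#' @export
ier_observed_info <- function(theta, lambda, sample) {
  check_params(theta, lambda)
  u <- unpack_sample(sample)
  xi2 <- 1 / u$x^2; Ci2 <- 1 / u$C^2
  lw <- log1mexp(lambda * xi2); lwC <- log1mexp(lambda * Ci2)
  g <- exp(-lambda * xi2 - lw); gC <- exp(-lambda * Ci2 - lwC)
  d2_tt <- -u$r / theta^2
  d2_tl <- sum((1 + u$R) * xi2 * g) + u$R_T * Ci2 * gC
  d2_ll <- -u$r / lambda^2 -
    sum((theta * (1 + u$R) - 1) * xi2^2 * g * (1 + g)) -
    theta * u$R_T * Ci2^2 * gC * (1 + gC)
  info <- -matrix(c(d2_tt, d2_tl, d2_tl, d2_ll), 2, 2,
                  dimnames = list(c("theta", "lambda"), c("theta", "lambda")))
  info
}

#' Profile maximum-likelihood estimate of the shape parameter
#'
#' For fixed \eqn{\lambda} the score in \eqn{\theta} has the closed-form root
#' \eqn{\hat\theta(\lambda) = r / Q_\lambda} with
#' \eqn{Q_\lambda = -[\sum (1+R_i)\log(1-e^{-\lambda x_i^{-2}}) +
#' R_T \log(1-e^{-\lambda C^{-2}})] > 0}, which reduces the two-parameter
#' maximization to a one-dimensional search in \eqn{\lambda}.
#'
#' @inheritParams ier_loglik
#' @return positive scalar \eqn{\hat\theta(\lambda)}.
#' @export
ier_profile_theta <- function(lambda, sample) {
  u <- unpack_sample(sample)
  if (any(lambda <= 0)) stop("'lambda' must be positive", call. = FALSE)
  vapply(lambda, function(l) {
    Q <- -(sum((1 + u$R) * log1mexp(l / u$x^2)) + u$R_T * log1mexp(l / u$C^2))
    u$r / Q
  }, numeric(1))
}

## Starting value heuristic: lambda from the theta = 1 median relation
## (F(x; 1, lambda) = 1/2 at x = sqrt(lambda/log 2)), theta from the profile.
start_values <- function(sample) {
  u <- unpack_sample(sample)
  lam0 <- stats::median(u$x)^2 * log(2)
  th0 <- ier_profile_theta(lam0, sample)
  c(theta = th0, lambda = lam0)
}

#' Fit the IER model to progressively hybrid censored data
#'
#' Maximum-likelihood (`method = "mle"`) or maximum-product-of-spacings
#' (`method = "mps"`) estimation of \eqn{(\theta, \lambda)} from a PHT-ICS
#' sample.  Optimization runs in \eqn{(\log\theta, \log\lambda)} with the
#' analytic gradient (BFGS, Nelder-Mead fallback), which enforces positivity
#' without constraints and is robust to the flat \eqn{\theta}-direction under
#' heavy censoring; for the MLE the fit is then polished through the profile
#' equation, and the two routes agree to optimizer tolerance.  Reliability
#' and hazard estimates at mission time `x0` follow by the invariance
#' property, with standard errors from the delta method (see
#' [ier_delta_se]).  Confidence intervals are reported on the natural scale
#' (`ACI-NA`, may cross zero) and on the log scale (`ACI-NL`, positive by
#' construction).
#'
#' @param sample a `phtics_sample` or complete numeric sample with at least
#'   two observed failures.
#' @param method `"mle"` or `"mps"`.
#' @param start optional `c(theta, lambda)` starting values; by default an
#'   internal heuristic is used and no user input is required.
#' @param x0 mission time(s) at which reliability and hazard are estimated.
#' @param level confidence level for the reported intervals.
#' @return An object of class `ier_fit`: list with `theta`, `lambda`, `se`
#'   (named vector), `cov` (2x2), `loglik` (value of the maximized
#'   objective), `method`, `converged`, `iterations`, `intervals` (data frame
#'   of ACI-NA/ACI-NL bounds for theta, lambda and, when `x0` is given,
#'   `R(x0)` and `H(x0)`), and `RH` (point estimates and delta-method
#'   standard errors at `x0`).
#' @examples
#' fit <- fit_ier(arthritis_relief())
#' c(fit$theta, fit$lambda)
#' @export
fit_ier <- function(sample, method = c("mle", "mps"), start = NULL, x0 = NULL,
                    level = 0.95) {
  method <- match.arg(method)
  u <- unpack_sample(sample)
  if (u$r < 2) stop("need at least two observed failures", call. = FALSE)
  if (is.numeric(sample)) sample <- unpack_to_phtics(sample)
  obj <- if (method == "mle") {
    list(f = function(th, la) ier_loglik(th, la, sample),
         g = function(th, la) ier_score(th, la, sample),
         info = function(th, la) ier_observed_info(th, la, sample))
  } else {
    list(f = function(th, la) ier_mps_objective(th, la, sample),
         g = function(th, la) ier_mps_gradient(th, la, sample),
         info = function(th, la) ier_mps_info(th, la, sample))
  }
  p0 <- if (is.null(start)) start_values(sample) else {
    check_params(start[1], start[2]); c(theta = start[1], lambda = start[2])
  }
  ## log-parameter objective; line searches may wander, so guard the domain
  negf <- function(lp) {
    if (any(!is.finite(lp)) || any(abs(lp) > 200)) return(1e10)
    v <- -obj$f(exp(lp[1]), exp(lp[2]))
    if (!is.finite(v)) 1e10 else v
  }
  negg <- function(lp) {
    if (any(!is.finite(lp)) || any(abs(lp) > 200)) return(c(0, 0))
    g <- -obj$g(exp(lp[1]), exp(lp[2])) * exp(lp)  # chain rule
    if (any(!is.finite(g))) c(0, 0) else g
  }
  opt <- stats::optim(log(p0), negf, negg, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  if (opt$convergence != 0) {
    opt2 <- stats::optim(opt$par, negf, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-14))
    if (opt2$value <= opt$value) opt <- opt2
  }
  th <- unname(exp(opt$par[1])); la <- unname(exp(opt$par[2]))
  if (method == "mle") {
    ## polish to machine precision through the profiled score equation:
    ## the lambda-score at theta = theta_hat(lambda) has a single root
    eq <- function(l) ier_score(ier_profile_theta(l, sample), l, sample)[2]
    lo <- la * 0.9; hi <- la * 1.1
    for (k in 1:30) {
      if (eq(lo) * eq(hi) <= 0) break
      lo <- lo * 0.8; hi <- hi * 1.25
    }
    root <- tryCatch(
      stats::uniroot(eq, c(lo, hi), tol = .Machine$double.eps^0.5)$root,
      error = function(e) NULL)
    if (!is.null(root)) {
      th2 <- ier_profile_theta(root, sample)
      if (obj$f(th2, root) >= obj$f(th, la)) {
        la <- root; th <- th2
      }
    }
  }
  grad <- obj$g(th, la)
  converged <- max(abs(grad * c(th, la))) < 1e-6  # log-scale gradient norm
  info <- obj$info(th, la)
  cov <- tryCatch(solve(info), error = function(e) {
    warning("observed information is singular (condition number ",
            format(kappa(info)), "); covariance unavailable")
    matrix(NA_real_, 2, 2)
  })
  dimnames(cov) <- dimnames(info)
  se <- sqrt(pmax(diag(cov), 0))
  ests <- c(theta = th, lambda = la)
  ints <- rbind(
    data.frame(quantity = c("theta", "lambda"), flavor = "ACI-NA",
               t(mapply(function(e, s) unlist(aci_normal(e, s, level)), ests, se))),
    data.frame(quantity = c("theta", "lambda"), flavor = "ACI-NL",
               t(mapply(function(e, s) unlist(aci_lognormal(e, s, level)), ests, se))))
  RH <- NULL
  if (!is.null(x0)) {
    RH <- data.frame(x = x0,
                     R = ier_reliability(x0, th, la),
                     H = ier_hazard(x0, th, la))
    dse <- t(vapply(x0, function(xx) ier_delta_se(th, la, cov, xx), numeric(2)))
    RH$se_R <- dse[, 1]; RH$se_H <- dse[, 2]
    for (k in seq_along(x0)) {
      ints <- rbind(ints,
        data.frame(quantity = sprintf("R(%g)", x0[k]), flavor = "ACI-NA",
                   t(unlist(aci_normal(RH$R[k], RH$se_R[k], level)))),
        data.frame(quantity = sprintf("R(%g)", x0[k]), flavor = "ACI-NL",
                   t(unlist(aci_lognormal(RH$R[k], RH$se_R[k], level)))),
        data.frame(quantity = sprintf("H(%g)", x0[k]), flavor = "ACI-NA",
                   t(unlist(aci_normal(RH$H[k], RH$se_H[k], level)))),
        data.frame(quantity = sprintf("H(%g)", x0[k]), flavor = "ACI-NL",
                   t(unlist(aci_lognormal(RH$H[k], RH$se_H[k], level)))))
    }
  }
  rownames(ints) <- NULL
  ints$length <- ints$upper - ints$lower
  structure(list(theta = th, lambda = la, se = se, cov = cov,
                 loglik = obj$f(th, la), method = toupper(method),
                 converged = converged, iterations = opt$counts[["function"]],
                 level = level, intervals = ints, RH = RH, sample = sample),
            class = "ier_fit")
}

unpack_to_phtics <- function(x) {
  n <- length(x)
  as_phtics(sort(x), censoring_plan(n, n, integer(n), threshold = max(x) * 2))
}

#' @export
print.ier_fit <- function(x, ...) {
  cat(sprintf("IER %s fit (%s): theta = %.4f (SE %.4f), lambda = %.4f (SE %.4f)\n",
              x$method, if (x$converged) "converged" else "NOT converged",
              x$theta, x$se[1], x$lambda, x$se[2]))
  cat(sprintf("objective = %.4f\n", x$loglik))
  if (!is.null(x$RH)) {
    for (k in seq_len(nrow(x$RH)))
      cat(sprintf("R(%g) = %.4f (SE %.4f), H(%g) = %.4f (SE %.4f)\n",
                  x$RH$x[k], x$RH$R[k], x$RH$se_R[k],
                  x$RH$x[k], x$RH$H[k], x$RH$se_H[k]))
  }
  print(x$intervals, digits = 5)
  invisible(x)
}

#' Asymptotic confidence intervals
#'
#' `aci_normal` is the Wald interval `estimate +/- z * se` (the lower bound
#' may be negative); `aci_lognormal` is its positivity-respecting log-scale
#' analogue `estimate * exp(+/- z * se / estimate)`.
#'
#' @param estimate point estimate (positive for `aci_lognormal`).
#' @param se non-negative standard error.
#' @param level confidence level in (0, 1).
#' @return list with `lower` and `upper`.
#' @export
aci_normal <- function(estimate, se, level = 0.95) {
  if (level <= 0 || level >= 1) stop("'level' must be in (0,1)", call. = FALSE)
  if (se < 0) stop("'se' must be non-negative", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(lower = estimate - z * se, upper = estimate + z * se)
}

#' @rdname aci_normal
#' @export
aci_lognormal <- function(estimate, se, level = 0.95) {
  if (estimate <= 0) stop("'estimate' must be positive", call. = FALSE)
  if (level <= 0 || level >= 1) stop("'level' must be in (0,1)", call. = FALSE)
  if (se < 0) stop("'se' must be non-negative", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(lower = estimate * exp(-z * se / estimate),
       upper = estimate * exp(z * se / estimate))
}

#' Delta-method standard errors for reliability and hazard estimates
#'
#' Propagates the parameter covariance to \eqn{\hat R(x)} and \eqn{\hat H(x)}
#' via the analytic gradients
#' \eqn{\partial R/\partial\theta = R \log w},
#' \eqn{\partial R/\partial\lambda = \theta x^{-2} e^{-\lambda x^{-2}} w^{\theta-1}},
#' \eqn{\partial H/\partial\theta = H/\theta} and
#' \eqn{\partial H/\partial\lambda = 2\theta x^{-3} e^{-\lambda x^{-2}}
#'   (1 - e^{-\lambda x^{-2}} - \lambda x^{-2}) / (1 - e^{-\lambda x^{-2}})^2}
#' with \eqn{w = 1 - e^{-\lambda x^{-2}}}.
#'
#' @inheritParams ier_loglik
#' @param cov 2x2 covariance matrix of `(theta, lambda)`.
#' @param x mission time.
#' @return length-2 vector `c(se_R, se_H)`.
#' @export
ier_delta_se <- function(theta, lambda, cov, x) {
  check_params(theta, lambda); check_x(x)
  y <- lambda / x^2
  lw <- log1mexp(y); w <- exp(lw); u <- exp(-y)
  R <- exp(theta * lw)
  H <- ier_hazard(x, theta, lambda)
  psiR <- c(R * lw, theta * x^-2 * u * exp((theta - 1) * lw))
  psiH <- c(H / theta, 2 * theta * x^-3 * u * (w - y) / w^2)
  vR <- drop(psiR %*% cov %*% psiR)
  vH <- drop(psiH %*% cov %*% psiH)
  c(se_R = sqrt(max(vR, 0)), se_H = sqrt(max(vH, 0)))
}
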