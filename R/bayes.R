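#' Independent gamma priors for the IER parameters
#'
#' \eqn{\theta \sim \mathrm{Gamma}(a, b)} and
#' \eqn{\lambda \sim \mathrm{Gamma}(c, d)} in the *rate* parameterization
#' (prior means `a/b` and `c/d`).  `ier_prior()` with no arguments gives the
#' near-noninformative choice with every hyperparameter 0.001.
#'
#' @param a,b shape and rate of the theta prior (positive).
#' @param c,d shape and rate of the lambda prior (positive).
#' @return object of class `ier_prior`.
#' @export
ier_prior <- function(a = 0.001, b = 0.001, c = 0.001, d = 0.001) {
  v <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("all hyperparameters must be positive", call. = FALSE)
  }
  structure(as.list(v), class = "ier_prior")
}

#' Log full conditional densities of the posterior
#'
#' Up to additive constants, the full conditional of \eqn{\theta} given
#' \eqn{\lambda} is the log kernel
#' \eqn{(a + r - 1)\log\theta - \theta (b + Q_\lambda)} — an exact
#' \eqn{\mathrm{Gamma}(a + r,\, b + Q_\lambda)} distribution, where
#' \eqn{Q_\lambda} is the profile-likelihood quantity of
#' [ier_profile_theta] — and the full conditional of \eqn{\lambda} is
#' \eqn{(c + r - 1)\log\lambda - \lambda(d + \sum x_i^{-2}) +
#'   \sum [\theta(1+R_i) - 1]\log w_i + \theta R_T \log w_C}.
#'
#' @inheritParams ier_loglik
#' @param prior an [ier_prior].
#' @return scalar log density (unnormalized).
#' @export
ier_logcond_theta <- function(theta, lambda, sample, prior) {
  stopifnot(inherits(prior, "ier_prior"))
  check_params(theta, lambda)
  u <- unpack_sample(sample)
  Q <- u$r / ier_profile_theta(lambda, sample)
  (prior$a + u$r - 1) * log(theta) - theta * (prior$b + Q)
}

#' @rdname ier_logcond_theta
#' @export
ier_logcond_lambda <- function(lambda, theta, sample, prior) {
  stopifnot(inherits(prior, "ier_prior"))
  check_params(theta, lambda)
  u <- unpack_sample(sample)
  lw <- log1mexp(lambda / u$x^2)
  lwC <- log1mexp(lambda / u$C^2)
  (prior$c + u$r - 1) * log(lambda) - lambda * (prior$d + sum(1 / u$x^2)) +
    sum((theta * (1 + u$R) - 1) * lw) + theta * u$R_T * lwC
}

#' Posterior sampling by Metropolis-Hastings within Gibbs
#'
#' Alternates single-site updates of \eqn{\theta} and \eqn{\lambda} from
#' their full conditionals.  With `sampler = "mh"` (default) both updates
#' are Gaussian random-walk Metropolis steps whose proposal standard
#' deviations default to the asymptotic standard errors of the MLEs (times
#' `proposal_scale`), with the chain initialized at the MLEs; non-positive
#' proposals are rejected outright since the target density vanishes there.
#' With `sampler = "gibbs"` the \eqn{\theta} update instead draws exactly
#' from its \eqn{\mathrm{Gamma}(a + r, b + Q_\lambda)} conditional — useful
#' as an independent cross-check of the Metropolis chain.  Per iteration the
#' reliability and hazard at mission time `x0` are recorded; the first
#' `burnin` iterations are discarded.
#'
#' @inheritParams ier_logcond_theta
#' @param n_iter total number of iterations.
#' @param burnin number of initial iterations discarded (`burnin < n_iter`).
#' @param x0 mission time for the derived reliability/hazard chains.
#' @param proposal_scale multiplier applied to both proposal standard
#'   deviations (default 1).
#' @param sampler `"mh"` or `"gibbs"` (exact gamma update for theta).
#' @param fit optional [fit_ier] MLE result used for initialization and
#'   proposal scales; computed internally when omitted.
#' @param start optional `c(theta, lambda)` overriding the MLE
#'   initialization.
#' @param seed optional integer seed applied locally.
#' @param thin keep every `thin`-th post-burn-in draw (default 1).
#' @return An object of class `ier_draws`: list with numeric vectors
#'   `theta`, `lambda`, `R`, `H` (post-burn-in chains), acceptance rates
#'   `accept_theta`, `accept_lambda`, the `x0`, `prior` and settings used.
#' @examples
#' s1 <- arthritis_phtics("S1")
#' draws <- ier_bayes(s1, n_iter = 2000, burnin = 500, seed = 1)
#' bayes_point(draws$theta)
#' @export
ier_bayes <- function(sample, prior = ier_prior(), n_iter = 12000,
                      burnin = 2000, x0 = 5, proposal_scale = 1,
                      sampler = c("mh", "gibbs"), fit = NULL, start = NULL,
                      seed = NULL, thin = 1L) {
  sampler <- match.arg(sampler)
  stopifnot(inherits(prior, "ier_prior"))
  if (burnin >= n_iter) stop("'burnin' must be smaller than 'n_iter'", call. = FALSE)
  u <- unpack_sample(sample)
  if (is.numeric(sample)) sample <- unpack_to_phtics(sample)
  if (is.null(fit)) fit <- fit_ier(sample, method = "mle")
  init <- if (is.null(start)) c(fit$theta, fit$lambda) else start
  check_params(init[1], init[2])
  sd_th <- fit$se[["theta"]] * proposal_scale
  sd_la <- fit$se[["lambda"]] * proposal_scale
  if (!all(is.finite(c(sd_th, sd_la))) || sd_th <= 0 || sd_la <= 0) {
    stop("proposal scales unavailable: MLE covariance is not finite", call. = FALSE)
  }
  local_seed(seed)
  xi2s <- sum(1 / u$x^2)
  a_r <- prior$a + u$r
  ## lambda-parts of the log conditionals, precomputable pieces
  logc_la <- function(la, th) ier_logcond_lambda(la, th, sample, prior)
  Qof <- function(la) u$r / ier_profile_theta(la, sample)
  th <- init[1]; la <- init[2]
  keep <- floor((n_iter - burnin) / thin)
  th_c <- la_c <- numeric(keep)
  acc_t <- acc_l <- 0L
  Q <- Qof(la)
  k <- 0L
  for (j in seq_len(n_iter)) {
    ## --- theta update ---
    if (sampler == "gibbs") {
      th <- stats::rgamma(1, shape = a_r, rate = prior$b + Q)
      acc_t <- acc_t + 1L
    } else {
      prop <- th + stats::rnorm(1, sd = sd_th)
      if (prop > 0) {
        lr <- (a_r - 1) * (log(prop) - log(th)) - (prop - th) * (prior$b + Q)
        if (log(stats::runif(1)) < lr) { th <- prop; acc_t <- acc_t + 1L }
      } else stats::runif(1)  # keep the stream aligned across accept paths
    }
    ## --- lambda update (always Metropolis; conditional is non-standard) ---
    prop <- la + stats::rnorm(1, sd = sd_la)
    if (prop > 0) {
      lcp <- logc_la(prop, th)
      lcc <- logc_la(la, th)
      if (log(stats::runif(1)) < lcp - lcc) {
        la <- prop
        Q <- Qof(la)
        acc_l <- acc_l + 1L
      }
    } else stats::runif(1)
    if (j > burnin && (j - burnin) %% thin == 0L) {
      k <- k + 1L
      th_c[k] <- th; la_c[k] <- la
    }
  }
  structure(list(theta = th_c, lambda = la_c,
                 R = ier_reliability(x0, th_c, la_c),
                 H = ier_hazard(x0, th_c, la_c),
                 accept_theta = acc_t / n_iter, accept_lambda = acc_l / n_iter,
                 x0 = x0, prior = prior, sampler = sampler,
                 n_iter = n_iter, burnin = burnin, thin = thin,
                 init = c(theta = init[1], lambda = init[2])),
            class = "ier_draws")
}

#' @export
print.ier_draws <- function(x, ...) {
  cat(sprintf("IER posterior draws (%s sampler): %d kept of %d (burn-in %d)\n",
              x$sampler, length(x$theta), x$n_iter, x$burnin))
  cat(sprintf("acceptance: theta %.2f, lambda %.2f\n",
              x$accept_theta, x$accept_lambda))
  cat(sprintf("posterior means: theta %.4f, lambda %.4f, R(%g) %.4f, H(%g) %.4f\n",
              mean(x$theta), mean(x$lambda), x$x0, mean(x$R), x$x0, mean(x$H)))
  invisible(x)
}

#' Bayes point estimates from posterior draws
#'
#' Squared-error loss gives the posterior mean; LINEX loss with shape `a`
#' gives \eqn{-a^{-1} \log E[e^{-a\xi}]}, computed through a log-sum-exp so
#' large `|a|` times large draws cannot overflow.  Positive `a` penalizes
#' overestimation (estimate below the mean), negative `a` the reverse.
#'
#' @param draws numeric vector of posterior draws.
#' @param loss `"se"` or `"linex"`.
#' @param a LINEX shape, required non-zero when `loss = "linex"`.
#' @return scalar estimate.
#' @export
bayes_point <- function(draws, loss = c("se", "linex"), a = NULL) {
  loss <- match.arg(loss)
  if (!length(draws)) stop("empty draws", call. = FALSE)
  if (loss == "se") return(mean(draws))
  if (is.null(a) || a == 0) stop("LINEX loss requires a non-zero 'a'", call. = FALSE)
  z <- -a * draws
  m <- max(z)
  -(m + log(mean(exp(z - m)))) / a
}

#' Credible intervals from posterior draws
#'
#' `equal_tailed_interval` returns the \eqn{(\gamma/2, 1-\gamma/2)} empirical
#' quantiles (type-7 interpolation).  `hpd_interval` returns the shortest
#' window containing a fraction `level` of the sorted draws: over all
#' contiguous windows of width \eqn{\lfloor \mathrm{level} \cdot M \rfloor}
#' the one with the smallest upper-minus-lower difference.
#'
#' @inheritParams bayes_point
#' @param level credibility level in (0, 1).
#' @return list with `lower` and `upper`.
#' @export
equal_tailed_interval <- function(draws, level = 0.95) {
  if (level <= 0 || level >= 1) stop("'level' must be in (0,1)", call. = FALSE)
  q <- stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 7)
  list(lower = q[1], upper = q[2])
}

#' @rdname equal_tailed_interval
#' @export
hpd_interval <- function(draws, level = 0.95) {
  if (level <= 0 || level >= 1) stop("'level' must be in (0,1)", call. = FALSE)
  M <- length(draws)
  w <- floor(level * M)
  if (w < 2) stop("too few draws for an HPD interval at this level", call. = FALSE)
  s <- sort(draws)
  nwin <- M - w
  if (nwin < 1) return(list(lower = s[1], upper = s[M]))
  widths <- s[(w + 1):M] - s[1:nwin]
  j <- which.min(widths)
  list(lower = s[j], upper = s[j + w])
}

#' Summary statistics of a posterior sample
#'
#' Mean, mode (argmax of a Gaussian kernel density estimate on a 512-point
#' grid), quartiles, standard deviation (n-1 denominator) and the moment
#' coefficient of skewness.
#'
#' @inheritParams bayes_point
#' @return data frame with one row: `mean`, `mode`, `q1`, `median`, `q3`,
#'   `sd`, `skewness`.
#' @export
posterior_summary <- function(draws) {
  if (!length(draws)) stop("empty draws", call. = FALSE)
  if (stats::sd(draws) == 0 || length(draws) < 2) {
    v <- draws[1]
    return(data.frame(mean = v, mode = v, q1 = v, median = v, q3 = v,
                      sd = 0, skewness = NaN))
  }
  dens <- stats::density(draws, n = 512)
  q <- stats::quantile(draws, c(0.25, 0.5, 0.75), names = FALSE)
  m <- mean(draws)
  s2 <- mean((draws - m)^2)
  data.frame(mean = m, mode = dens$x[which.max(dens$y)],
             q1 = q[1], median = q[2], q3 = q[3],
             sd = stats::sd(draws),
             skewness = mean((draws - m)^3) / s2^1.5)
}
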