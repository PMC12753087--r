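#' Monte-Carlo study design
#'
#' Bundles everything a simulation cell grid needs: the true parameters, the
#' hybrid thresholds, `(n, m)` pairs, removal schemes, replicate count,
#' priors and LINEX shapes for the Bayes estimators, MCMC settings, interval
#' level, the mission time at which reliability and hazard are assessed, and
#' the master seed from which all per-replicate seeds are derived.
#'
#' @param theta,lambda true IER parameters.
#' @param T_values numeric vector of hybrid thresholds.
#' @param nm_pairs list of `c(n, m)` pairs.
#' @param schemes character vector of removal schemes (see
#'   [censoring_scheme]).
#' @param reps replicates per cell.
#' @param estimators subset of `c("mle", "mps", "bayes")` to evaluate;
#'   dropping `"bayes"` makes large grids fast.
#' @param priors list of [ier_prior] objects (used when `"bayes"` is
#'   requested).
#' @param linex_a numeric vector of LINEX shapes.
#' @param n_iter,burnin MCMC settings per replicate.
#' @param level interval level.
#' @param x0 mission time.
#' @param seed master seed.
#' @return object of class `simulation_design`.
#' @export
simulation_design <- function(theta = 0.4, lambda = 0.8,
                              T_values = c(1.5, 2.5),
                              nm_pairs = list(c(40, 20), c(40, 32),
                                              c(80, 40), c(80, 64)),
                              schemes = c("scheme1", "scheme2", "scheme3"),
                              reps = 1000,
                              estimators = c("mle", "mps", "bayes"),
                              priors = list(`Prior-1` = ier_prior(2, 5, 4, 5),
                                            `Prior-2` = ier_prior(4, 10, 8, 10)),
                              linex_a = c(-2, 2),
                              n_iter = 12000, burnin = 2000,
                              level = 0.95, x0 = 0.5, seed = 1L) {
  check_params(theta, lambda)
  estimators <- match.arg(estimators, several.ok = TRUE)
  stopifnot(reps >= 1, x0 > 0)
  structure(list(theta = theta, lambda = lambda, T_values = T_values,
                 nm_pairs = nm_pairs, schemes = schemes, reps = reps,
                 estimators = estimators, priors = priors, linex_a = linex_a,
                 n_iter = n_iter, burnin = burnin, level = level, x0 = x0,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

## One replicate of one cell: generate (redrawing d = 0 cases), fit the
## requested estimators, return a named list of point estimates and interval
## bounds for theta, lambda, R(x0), H(x0).
mc_replicate <- function(plan, design, rep_seed) {
  s <- NULL
  redraws <- -1L
  seed <- rep_seed
  while (is.null(s)) {
    redraws <- redraws + 1L
    s <- tryCatch(rphtics(plan, design$theta, design$lambda, seed = seed),
                  error = function(e) NULL)
    seed <- seed + 1L
    if (redraws > 100) stop("too many degenerate (d = 0) replicates", call. = FALSE)
  }
  out <- list(redraws = redraws, r = s$r, case = s$case)
  x0 <- design$x0
  fits <- list()
  for (m in intersect(design$estimators, c("mle", "mps"))) {
    f <- tryCatch(fit_ier(s, method = m, x0 = x0, level = design$level),
                  error = function(e) NULL)
    fits[[m]] <- f
    if (is.null(f)) next
    na <- f$intervals[f$intervals$flavor == "ACI-NA", ]
    out[[m]] <- list(
      est = c(theta = f$theta, lambda = f$lambda, R = f$RH$R[1], H = f$RH$H[1]),
      ci = rbind(theta = unlist(na[na$quantity == "theta", c("lower", "upper")]),
                 lambda = unlist(na[na$quantity == "lambda", c("lower", "upper")]),
                 R = unlist(na[grepl("^R", na$quantity), c("lower", "upper")]),
                 H = unlist(na[grepl("^H", na$quantity), c("lower", "upper")])))
  }
  if ("bayes" %in% design$estimators) {
    basefit <- fits$mle
    if (is.null(basefit)) basefit <- tryCatch(fit_ier(s, x0 = x0), error = function(e) NULL)
    out$bayes <- list()
    if (!is.null(basefit) && all(is.finite(basefit$se)) && all(basefit$se > 0)) {
      for (pn in names(design$priors)) {
        dr <- tryCatch(
          ier_bayes(s, prior = design$priors[[pn]], n_iter = design$n_iter,
                    burnin = design$burnin, x0 = x0, fit = basefit,
                    seed = seed + 1000L),
          error = function(e) NULL)
        if (is.null(dr)) next
        chains <- list(theta = dr$theta, lambda = dr$lambda, R = dr$R, H = dr$H)
        pt <- lapply(chains, function(ch) {
          c(se = bayes_point(ch),
            stats::setNames(vapply(design$linex_a,
                                   function(aa) bayes_point(ch, "linex", aa),
                                   numeric(1)),
                            paste0("linex", design$linex_a)))
        })
        hpd <- t(vapply(chains, function(ch) unlist(hpd_interval(ch, design$level)),
                        numeric(2)))
        out$bayes[[pn]] <- list(est = pt, hpd = hpd)
      }
    }
  }
  out
}

#' Run a Monte-Carlo evaluation of the estimators
#'
#' For every cell (threshold x `(n, m)` x scheme) of `design`, generates
#' `reps` PHT-ICS samples from the true IER model, fits the requested
#' estimators, and aggregates average point estimates, RMSE and mean
#' relative absolute bias for \eqn{\theta}, \eqn{\lambda}, \eqn{R(x_0)} and
#' \eqn{H(x_0)}, plus average length and coverage of the ACI-NA (MLE, MPS)
#' and HPD (Bayes) intervals.  Replicates whose truncation leaves no
#' observed failure are redrawn with the next derived seed and counted in
#' the `redraws` column; replicate seeds are `seed + 1000 * replicate
#' index`, so cells and replicates are individually reproducible.
#'
#' @param design a [simulation_design].
#' @param progress logical; print one line per cell.
#' @return data frame in long format: one row per cell x estimator x
#'   estimand x metric, with columns `T`, `n`, `m`, `scheme`, `estimator`,
#'   `estimand`, `metric`, `value`, `mc_se` (Monte-Carlo standard error
#'   where defined), `reps`, `redraws`, `fit_failures`.
#' @examples
#' d <- simulation_design(T_values = 1.5, nm_pairs = list(c(40, 20)),
#'                        schemes = "scheme1", reps = 25,
#'                        estimators = "mle", seed = 7)
#' run_monte_carlo(d, progress = FALSE)
#' @export
run_monte_carlo <- function(design, progress = interactive()) {
  stopifnot(inherits(design, "simulation_design"))
  truth <- c(theta = design$theta, lambda = design$lambda,
             R = ier_reliability(design$x0, design$theta, design$lambda),
             H = ier_hazard(design$x0, design$theta, design$lambda))
  rows <- list()
  cell_id <- 0L
  for (Tt in design$T_values) for (nm in design$nm_pairs) for (sch in design$schemes) {
    cell_id <- cell_id + 1L
    n <- nm[1]; m <- nm[2]
    plan <- censoring_plan(n, m, censoring_scheme(sch, n, m), threshold = Tt)
    reps <- lapply(seq_len(design$reps), function(i) {
      mc_replicate(plan, design, design$seed + 1000L * (i + design$reps * (cell_id - 1L)))
    })
    redraws <- sum(vapply(reps, `[[`, numeric(1), "redraws"))
    add_row <- function(estimator, estimand, metric, value, mc_se, failures) {
      rows[[length(rows) + 1L]] <<- data.frame(
        T = Tt, n = n, m = m, scheme = sch, estimator = estimator,
        estimand = estimand, metric = metric, value = value, mc_se = mc_se,
        reps = design$reps, redraws = redraws, fit_failures = failures)
    }
    for (meth in intersect(design$estimators, c("mle", "mps"))) {
      ok <- !vapply(reps, function(z) is.null(z[[meth]]), logical(1))
      failures <- sum(!ok)
      for (par in names(truth)) {
        est <- vapply(reps[ok], function(z) z[[meth]]$est[[par]], numeric(1))
        ci <- t(vapply(reps[ok], function(z) z[[meth]]$ci[par, ], numeric(2)))
        nrep <- length(est)
        add_row(toupper(meth), par, "APE", metric_ape(est, truth[[par]]),
                stats::sd(est) / sqrt(nrep), failures)
        add_row(toupper(meth), par, "RMSE", metric_rmse(est, truth[[par]]), NA, failures)
        add_row(toupper(meth), par, "MRAB", metric_mrab(est, truth[[par]]), NA, failures)
        add_row(toupper(meth), par, "ACL", metric_acl(ci, truth[[par]]),
                stats::sd(ci[, 2] - ci[, 1]) / sqrt(nrep), failures)
        add_row(toupper(meth), par, "CP", metric_cp(ci, truth[[par]]), NA, failures)
      }
    }
    if ("bayes" %in% design$estimators) {
      for (pn in names(design$priors)) {
        ok <- vapply(reps, function(z) !is.null(z$bayes[[pn]]), logical(1))
        failures <- sum(!ok)
        if (!any(ok)) next
        losses <- names(reps[which(ok)[1]][[1]]$bayes[[pn]]$est$theta)
        for (par in names(truth)) {
          for (lo in losses) {
            est <- vapply(reps[ok], function(z) z$bayes[[pn]]$est[[par]][[lo]],
                          numeric(1))
            lab <- sprintf("Bayes-%s-%s", pn, toupper(lo))
            add_row(lab, par, "APE", metric_ape(est, truth[[par]]),
                    stats::sd(est) / sqrt(length(est)), failures)
            add_row(lab, par, "RMSE", metric_rmse(est, truth[[par]]), NA, failures)
            add_row(lab, par, "MRAB", metric_mrab(est, truth[[par]]), NA, failures)
          }
          hpd <- t(vapply(reps[ok], function(z) z$bayes[[pn]]$hpd[par, ], numeric(2)))
          lab <- sprintf("HPD-%s", pn)
          add_row(lab, par, "ACL", metric_acl(hpd, truth[[par]]),
                  stats::sd(hpd[, 2] - hpd[, 1]) / sqrt(nrow(hpd)), failures)
          add_row(lab, par, "CP", metric_cp(hpd, truth[[par]]), NA, failures)
        }
      }
    }
    if (progress) {
      message(sprintf("cell T=%g (n,m)=(%d,%d) %s done (%d redraws)",
                      Tt, n, m, sch, redraws))
    }
  }
  do.call(rbind, rows)
}

#' Full analysis of one censored dataset
#'
#' Runs the complete single-dataset workflow: maximum-likelihood and
#' maximum-product-of-spacings fits with standard errors and ACI-NA/ACI-NL
#' intervals, Bayesian sampling under the given prior with squared-error and
#' LINEX point estimates, equal-tailed and HPD credible intervals, and
#' posterior summary statistics for \eqn{\theta}, \eqn{\lambda},
#' \eqn{R(x_0)} and \eqn{H(x_0)}.
#'
#' @param sample a `phtics_sample` (e.g. from [arthritis_phtics]) or a
#'   complete numeric sample.
#' @param x0 mission time.
#' @param prior an [ier_prior]; defaults to near-noninformative.
#' @param linex_a LINEX shapes for the Bayes point estimates.
#' @param n_iter,burnin MCMC settings.
#' @param level interval level.
#' @param seed integer seed for the MCMC run.
#' @return list of class `ier_report` with elements `mle`, `mps`
#'   ([fit_ier] objects), `draws` ([ier_bayes] output), `estimates` (data
#'   frame of point estimates per method), `intervals` (data frame of
#'   ACI-NA/ACI-NL/BCI/HPD bounds) and `posterior` (summary statistics per
#'   estimand).
#' @export
real_data_report <- function(sample, x0 = 5, prior = ier_prior(),
                             linex_a = c(-3, -0.03, 3), n_iter = 50000,
                             burnin = 10000, level = 0.95, seed = 1L) {
  mle <- fit_ier(sample, "mle", x0 = x0, level = level)
  mps <- fit_ier(sample, "mps", x0 = x0, level = level)
  draws <- ier_bayes(sample, prior = prior, n_iter = n_iter, burnin = burnin,
                     x0 = x0, fit = mle, seed = seed)
  chains <- list(theta = draws$theta, lambda = draws$lambda,
                 R = draws$R, H = draws$H)
  names(chains)[3:4] <- c(sprintf("R(%g)", x0), sprintf("H(%g)", x0))
  est <- do.call(rbind, lapply(names(chains), function(nm) {
    ch <- chains[[nm]]
    data.frame(quantity = nm,
               MLE = c(theta = mle$theta, lambda = mle$lambda,
                       mle$RH$R[1], mle$RH$H[1])[[match(nm, names(chains))]],
               MPS = c(mps$theta, mps$lambda, mps$RH$R[1], mps$RH$H[1])[[match(nm, names(chains))]],
               SE_loss = bayes_point(ch),
               t(stats::setNames(vapply(linex_a, function(aa) bayes_point(ch, "linex", aa),
                                        numeric(1)),
                                 paste0("LINEX_", linex_a))),
               posterior_sd = stats::sd(ch))
  }))
  ints <- do.call(rbind, lapply(names(chains), function(nm) {
    ch <- chains[[nm]]
    bci <- equal_tailed_interval(ch, level)
    hpd <- hpd_interval(ch, level)
    rbind(data.frame(quantity = nm, flavor = "BCI", lower = bci$lower,
                     upper = bci$upper, length = bci$upper - bci$lower),
          data.frame(quantity = nm, flavor = "HPD", lower = hpd$lower,
                     upper = hpd$upper, length = hpd$upper - hpd$lower))
  }))
  ints <- rbind(cbind(method = "MLE", mle$intervals),
                cbind(method = "MPS", mps$intervals),
                cbind(method = "Bayes", ints))
  post <- do.call(rbind, lapply(names(chains), function(nm) {
    cbind(quantity = nm, posterior_summary(chains[[nm]]))
  }))
  structure(list(mle = mle, mps = mps, draws = draws, estimates = est,
                 intervals = ints, posterior = post, x0 = x0, level = level),
            class = "ier_report")
}

#' @export
print.ier_report <- function(x, ...) {
  cat("== IER PHT-ICS analysis ==\n\nPoint estimates:\n")
  print(x$estimates, digits = 5, row.names = FALSE)
  cat("\nIntervals:\n")
  print(x$intervals, digits = 5, row.names = FALSE)
  cat("\nPosterior summaries:\n")
  print(x$posterior, digits = 5, row.names = FALSE)
  invisible(x)
}
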