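test_that("Monte-Carlo metrics match hand-computed values", {
  expect_equal(metric_ape(c(0.4, 0.4), 0.4), 0.4)
  expect_equal(metric_rmse(c(0.4, 0.4), 0.4), 0)
  expect_equal(metric_mrab(c(0.4, 0.4), 0.4), 0)
  expect_equal(metric_rmse(c(0.3, 0.5), 0.4), 0.1)
  expect_equal(metric_mrab(c(0.3, 0.5), 0.4), 0.25)
  # bias-variance inequality
  set.seed(2)
  for (k in 1:10) {
    e <- stats::rnorm(20, 0.5, 0.2)
    expect_gte(metric_rmse(e, 0.4), abs(metric_ape(e, 0.4) - 0.4))
  }
  ints <- cbind(c(-0.6, -0.6, -0.6), c(1.4, 1.4, 1.4))
  expect_equal(metric_acl(ints, 0.4), 2)
  expect_equal(metric_cp(ints, 0.4), 100)
  expect_equal(metric_cp(cbind(1, 2), 0.4), 0)
  expect_equal(metric_cp(rbind(c(0, 1), c(2, 3), c(0.3, 0.5)), 0.4),
               100 * 2 / 3)
  expect_error(metric_mrab(1, 0), "truth = 0")
})

test_that("a single-replicate study returns that replicate's values", {
  d <- simulation_design(T_values = 1.5, nm_pairs = list(c(40, 20)),
                         schemes = "scheme1", reps = 1, estimators = "mle",
                         seed = 5)
  tab <- run_monte_carlo(d, progress = FALSE)
  s <- rphtics(sim_plan(), 0.4, 0.8, seed = 5 + 1000)
  f <- fit_ier(s, x0 = 0.5)
  expect_equal(tab$value[tab$estimand == "theta" & tab$metric == "APE"], f$theta)
  expect_equal(tab$value[tab$estimand == "theta" & tab$metric == "RMSE"],
               abs(f$theta - 0.4))
  expect_equal(tab$value[tab$estimand == "H" & tab$metric == "APE"], f$RH$H[1])
  expect_true(all(tab$value[tab$metric == "CP"] %in% c(0, 100)))
})

test_that("the study engine covers Bayes estimators and interval metrics", {
  d <- simulation_design(T_values = 1.5, nm_pairs = list(c(40, 20)),
                         schemes = "scheme1", reps = 8,
                         estimators = c("mle", "bayes"),
                         priors = list(P1 = ier_prior(2, 5, 4, 5)),
                         linex_a = c(-2, 2), n_iter = 1500, burnin = 300,
                         seed = 9)
  tab <- run_monte_carlo(d, progress = FALSE)
  expect_true(any(grepl("Bayes-P1-SE", tab$estimator)))
  expect_true(any(grepl("Bayes-P1-LINEX2", tab$estimator)))
  expect_true(any(tab$estimator == "HPD-P1"))
  expect_true(all(tab$value[tab$metric == "ACL"] >= 0))
  expect_true(all(tab$value[tab$metric == "CP"] >= 0 &
                    tab$value[tab$metric == "CP"] <= 100))
  expect_true(all(tab$value[tab$metric %in% c("RMSE", "MRAB")] >= 0))
})

test_that("error under censoring shrinks as the failure budget grows", {
  base <- list(T_values = 1.5, schemes = "scheme1", reps = 60,
               estimators = "mle", seed = 13)
  t20 <- do.call(simulation_design, c(base, list(nm_pairs = list(c(40, 20)))))
  t32 <- do.call(simulation_design, c(base, list(nm_pairs = list(c(40, 32)))))
  r20 <- run_monte_carlo(t20, progress = FALSE)
  r32 <- run_monte_carlo(t32, progress = FALSE)
  pick <- function(tab) tab$value[tab$estimand == "theta" & tab$metric == "RMSE"]
  expect_lt(pick(r32), pick(r20))
})

test_that("K-S statistic matches the ecdf-jump enumeration and the stats oracle", {
  x <- rier(40, 0.6, 1.1, seed = 71)
  g <- ks_gof(x, 0.6, 1.1)
  # brute force over the 2n jump comparisons
  n <- length(x); xs <- sort(x)
  Ds <- max(vapply(seq_len(n), function(i) {
    max(abs(i / n - pier(xs[i], 0.6, 1.1)), abs((i - 1) / n - pier(xs[i], 0.6, 1.1)))
  }, numeric(1)))
  expect_equal(g$statistic, Ds)
  ks <- suppressWarnings(stats::ks.test(x, function(q) pier(q, 0.6, 1.1),
                                        exact = FALSE))
  expect_equal(g$statistic, unname(ks$statistic))
  expect_equal(g$p.value, ks$p.value, tolerance = 1e-3)
  # data generated from the model: statistic tends to zero
  big <- rier(1e5, 0.6, 1.1, seed = 72)
  expect_lt(ks_gof(big, 0.6, 1.1)$statistic, 0.01)
})

test_that("empirical reliability is the complement of the ecdf", {
  Rn <- empirical_reliability(arthritis_relief())
  expect_equal(Rn(1), 1)
  expect_equal(Rn(100), 0)
  expect_equal(Rn(5.0), 34 / 50)   # proportion strictly above 5.0
  x <- c(1, 2, 3, 4)
  Rn2 <- empirical_reliability(x)
  expect_equal(Rn2(x), (4 - seq_len(4)) / 4)
})

test_that("the likelihood surface has its grid maximum at the fit", {
  x <- arthritis_relief()
  f <- fit_ier(x)
  g <- loglik_grid(x, c(0.8, 1.5) * f$theta, c(0.8, 1.5) * f$lambda,
                   resolution = 41)
  expect_true(all(g$loglik <= f$loglik))
  idx <- which(g$loglik == max(g$loglik), arr.ind = TRUE)
  expect_lt(abs(g$theta[idx[1]] - f$theta), diff(g$theta[1:2]) * 1.5)
  expect_lt(abs(g$lambda[idx[2]] - f$lambda), diff(g$lambda[1:2]) * 1.5)
  # single connected superlevel set near the maximum (unimodal ridge)
  top <- g$loglik >= f$loglik - 2
  cc <- which(top, arr.ind = TRUE)
  expect_true(all(abs(diff(sort(unique(cc[, 1])))) == 1))
})

test_that("the single-dataset report is reproducible and internally consistent", {
  s4 <- arthritis_phtics("S4")
  rep1 <- real_data_report(s4, n_iter = 3000, burnin = 600, seed = 3)
  rep2 <- real_data_report(s4, n_iter = 3000, burnin = 600, seed = 3)
  expect_identical(rep1$estimates, rep2$estimates)
  expect_identical(rep1$intervals, rep2$intervals)
  expect_equal(rep1$estimates$MLE[1], rep1$mle$theta)
  hpd <- subset(rep1$intervals, flavor == "HPD")
  bci <- subset(rep1$intervals, flavor == "BCI")
  expect_true(all(hpd$length <= bci$length + 1e-12))
  expect_true(all(rep1$posterior$q1 <= rep1$posterior$median &
                    rep1$posterior$median <= rep1$posterior$q3))
})
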