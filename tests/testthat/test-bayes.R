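test_that("full conditionals are the joint posterior up to additive constants", {
  s1 <- arthritis_phtics("S1")
  pr <- ier_prior(2, 5, 4, 5)
  logpost <- function(th, la) {
    ier_loglik(th, la, s1) + (pr$a - 1) * log(th) - pr$b * th +
      (pr$c - 1) * log(la) - pr$d * la
  }
  pts <- random_params(20, lo = 0.5, hi = 3, seed = 14)
  # theta conditional: difference from the joint must not depend on theta
  la0 <- 40
  d <- vapply(pts[, 1], function(th) {
    logpost(th, la0) - ier_logcond_theta(th, la0, s1, pr)
  }, numeric(1))
  expect_lt(diff(range(d)), 1e-8)
  # lambda conditional likewise
  th0 <- 1.2
  d2 <- vapply(pts[, 2] * 20, function(la) {
    logpost(th0, la) - ier_logcond_lambda(la, th0, s1, pr)
  }, numeric(1))
  expect_lt(diff(range(d2)), 1e-8)
})

test_that("theta conditional is the exact gamma kernel with the profile rate", {
  s1 <- arthritis_phtics("S1")
  pr <- ier_prior(2, 5, 4, 5)
  la <- 40
  Q <- s1$r / ier_profile_theta(la, s1)
  th <- seq(0.3, 4, length.out = 120)
  lc <- vapply(th, function(t) ier_logcond_theta(t, la, s1, pr), numeric(1))
  ref <- stats::dgamma(th, shape = pr$a + s1$r, rate = pr$b + Q, log = TRUE)
  expect_lt(diff(range(lc - ref)), 1e-10)
  # analytic mode of the gamma kernel
  expect_equal(th[which.max(lc)], (pr$a + s1$r - 1) / (pr$b + Q), tolerance = 0.05)
  expect_true(all(diff(lc[th < (pr$a + s1$r - 1) / (pr$b + Q)]) > 0))
})

test_that("lambda conditional reduces to a gamma kernel without censoring at theta 1", {
  x <- rier(12, 1, 2, seed = 15)
  s <- ierphc:::unpack_to_phtics(x)
  pr <- ier_prior(1.5, 2, 2.5, 3)
  la <- seq(0.5, 6, length.out = 80)
  lc <- vapply(la, function(l) ier_logcond_lambda(l, 1, s, pr), numeric(1))
  ref <- stats::dgamma(la, shape = pr$c + s$r, rate = pr$d + sum(1 / x^2), log = TRUE)
  expect_lt(diff(range(lc - ref)), 1e-10)
  # stability across a wide lambda range on the real fixture
  s1 <- arthritis_phtics("S1")
  wide <- vapply(10^seq(-6, 3, by = 0.5),
                 function(l) ier_logcond_lambda(l, 1.3, s1, ier_prior()), numeric(1))
  expect_true(all(is.finite(wide)))
})

test_that("Metropolis chain agrees with the conjugate-Gibbs oracle and is reproducible", {
  s1 <- arthritis_phtics("S1")
  mh <- ier_bayes(s1, n_iter = 12000, burnin = 2000, x0 = 5, seed = 31)
  gb <- ier_bayes(s1, n_iter = 12000, burnin = 2000, x0 = 5, seed = 32,
                  sampler = "gibbs")
  expect_identical(ier_bayes(s1, n_iter = 3000, burnin = 500, seed = 31)$theta,
                   ier_bayes(s1, n_iter = 3000, burnin = 500, seed = 31)$theta)
  mcse <- function(x, nb = 40) {
    b <- floor(length(x) / nb)
    stats::sd(colMeans(matrix(x[1:(nb * b)], b))) / sqrt(nb)
  }
  for (par in c("theta", "lambda")) {
    se <- sqrt(mcse(mh[[par]])^2 + mcse(gb[[par]])^2)
    expect_lt(abs(mean(mh[[par]]) - mean(gb[[par]])), 4 * se)
  }
  expect_true(mh$accept_theta > 0.05 && mh$accept_theta < 0.95)
  expect_true(all(mh$theta > 0) && all(mh$lambda > 0))
  expect_length(mh$theta, 10000)
})

test_that("posterior concentrates on the MLE under flat priors and ample data", {
  x <- rier(2000, 0.4, 0.8, seed = 44)
  f <- fit_ier(x)
  d <- ier_bayes(x, prior = ier_prior(), n_iter = 6000, burnin = 1000,
                 x0 = 0.5, fit = f, seed = 45)
  expect_lt(abs(mean(d$theta) - f$theta) / f$theta, 0.02)
  expect_lt(abs(mean(d$lambda) - f$lambda) / f$lambda, 0.02)
})

test_that("loss-based point estimates obey the LINEX limit and Jensen ordering", {
  set.seed(17)
  draws <- stats::rgamma(5000, 3, 2)
  se <- bayes_point(draws)
  expect_equal(se, mean(draws))
  expect_equal(bayes_point(draws, "linex", 1e-8), se, tolerance = 1e-6)
  expect_lte(bayes_point(draws, "linex", 2), se)
  expect_gte(bayes_point(draws, "linex", -2), se)
  # degenerate chain: every loss returns the constant
  expect_equal(bayes_point(rep(2.5, 10)), 2.5)
  expect_equal(bayes_point(rep(2.5, 10), "linex", 3), 2.5)
  # overflow guard: huge draws times large |a|
  expect_true(is.finite(bayes_point(draws * 500, "linex", -3)))
  expect_error(bayes_point(draws, "linex", 0), "non-zero")
  expect_error(bayes_point(numeric(0)), "empty")
})

test_that("credible intervals match their definitions and HPD is the shortest window", {
  draws <- as.numeric(1:100)
  et <- equal_tailed_interval(draws, 0.95)
  expect_equal(et$lower, stats::quantile(draws, 0.025, names = FALSE))
  expect_equal(et$upper, stats::quantile(draws, 0.975, names = FALSE))
  expect_true(et$lower <= stats::median(draws) && stats::median(draws) <= et$upper)
  # brute-force oracle over every contiguous window
  set.seed(23)
  for (k in 1:20) {
    d <- stats::rgamma(300 + k, 2, 1)
    h <- hpd_interval(d, 0.9)
    s <- sort(d)
    w <- floor(0.9 * length(d))
    cand <- vapply(seq_len(length(d) - w), function(j) s[j + w] - s[j], numeric(1))
    jstar <- which.min(cand)
    expect_identical(c(h$lower, h$upper), c(s[jstar], s[jstar + w]))
    et2 <- equal_tailed_interval(d, 0.9)
    expect_lte(h$upper - h$lower, et2$upper - et2$lower)
    expect_gt(h$lower, 0)
  }
  # symmetric unimodal draws: HPD and equal-tailed nearly coincide
  z <- stats::rnorm(50000)
  h <- hpd_interval(z, 0.95); e <- equal_tailed_interval(z, 0.95)
  expect_lt(abs((h$upper - h$lower) - (e$upper - e$lower)) / (e$upper - e$lower),
            0.02)
})

test_that("posterior summaries report the stated statistics", {
  set.seed(29)
  z <- stats::rnorm(1e5, 3, 2)
  ps <- posterior_summary(z)
  expect_lt(abs(ps$skewness), 0.05)
  expect_equal(ps$mean, mean(z))
  expect_equal(ps$sd, stats::sd(z))
  expect_true(ps$q1 <= ps$median && ps$median <= ps$q3)
  expect_equal(ps$mode, 3, tolerance = 0.2)
  const <- posterior_summary(rep(7, 50))
  expect_equal(const$sd, 0)
  expect_equal(const$mode, 7)
})
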