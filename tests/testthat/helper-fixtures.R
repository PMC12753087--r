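# Shared fixtures built in code.

# benchmark simulation plan: n = 40, m = 20, all removals at the first
# failure, hybrid threshold 1.5
sim_plan <- function(n = 40, m = 20, scheme = "scheme1", threshold = 1.5) {
  censoring_plan(n, m, censoring_scheme(scheme, n, m), threshold)
}

# a tie-free censored sample from the benchmark truth (0.4, 0.8)
sim_sample <- function(seed = 11, ...) {
  rphtics(sim_plan(...), theta = 0.4, lambda = 0.8, seed = seed)
}

# central finite differences, independent of any analytic gradient code
fd_grad <- function(f, p, h = 1e-6) {
  vapply(seq_along(p), function(i) {
    e <- replace(numeric(length(p)), i, h * max(1, abs(p[i])))
    (f(p + e) - f(p - e)) / (2 * e[i])
  }, numeric(1))
}

fd_hess <- function(f, p, h = 1e-5) {
  k <- length(p)
  H <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ei <- replace(numeric(k), i, h * max(1, abs(p[i])))
    ej <- replace(numeric(k), j, h * max(1, abs(p[j])))
    H[i, j] <- (f(p + ei + ej) - f(p + ei - ej) - f(p - ei + ej) + f(p - ei - ej)) /
      (4 * ei[i] * ej[j])
  }
  (H + t(H)) / 2
}

# random valid parameter points, log-uniform over a broad range
random_params <- function(k, lo = 0.2, hi = 5, seed = 1) {
  set.seed(seed)
  cbind(theta = exp(stats::runif(k, log(lo), log(hi))),
        lambda = exp(stats::runif(k, log(lo), log(hi))))
}
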