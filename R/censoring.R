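#' Progressive hybrid Type-I censoring plans
#'
#' A censoring plan describes the design of a progressively censored life
#' test with a hybrid Type-I time limit: `n` units go on test, `removals[i]`
#' surviving units are withdrawn at the i-th observed failure, the test stops
#' at the m-th failure or at the threshold time `threshold`, whichever comes
#' first.
#'
#' @param n number of units on test.
#' @param m planned number of observed failures (`m <= n`).
#' @param removals integer vector of length `m` of planned withdrawals
#'   \eqn{R_1, \dots, R_m}; must satisfy \eqn{\sum R_i = n - m}.
#' @param threshold positive time limit \eqn{T} of the hybrid design.
#'
#' @return An object of class `censoring_plan` with fields `n`, `m`,
#'   `removals` and `threshold`.
#' @examples
#' censoring_plan(40, 20, censoring_scheme("scheme1", 40, 20), threshold = 1.5)
#' @export
censoring_plan <- function(n, m, removals, threshold) {
  n <- as.integer(n); m <- as.integer(m)
  if (m < 1 || n < 1 || m > n) stop("need 1 <= m <= n", call. = FALSE)
  removals <- as.integer(removals)
  if (length(removals) != m) stop("'removals' must have length m", call. = FALSE)
  if (any(removals < 0)) stop("removals must be non-negative", call. = FALSE)
  if (sum(removals) != n - m) {
    stop(sprintf("sum(removals) must equal n - m = %d (got %d)", n - m, sum(removals)),
         call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold) ||
      threshold <= 0) {
    stop("'threshold' must be a positive time", call. = FALSE)
  }
  structure(list(n = n, m = m, removals = removals, threshold = as.numeric(threshold)),
            class = "censoring_plan")
}

#' @export
print.censoring_plan <- function(x, ...) {
  cat(sprintf("Progressive hybrid Type-I censoring plan: n = %d, m = %d, T = %g\n",
              x$n, x$m, x$threshold))
  cat("removals:", x$removals, "\n")
  invisible(x)
}

#' Standard one-point removal schemes
#'
#' The three benchmark removal patterns used in the simulation study:
#' all `n - m` withdrawals at the first failure (`scheme1`), at the middle
#' failure `ceiling(m/2)` (`scheme2`), or at the last failure (`scheme3`).
#'
#' @param kind one of `"scheme1"`, `"scheme2"`, `"scheme3"`.
#' @inheritParams censoring_plan
#' @return integer removal vector of length `m` summing to `n - m`.
#' @examples
#' censoring_scheme("scheme1", 40, 20)
#' @export
censoring_scheme <- function(kind = c("scheme1", "scheme2", "scheme3"), n, m) {
  kind <- match.arg(kind)
  n <- as.integer(n); m <- as.integer(m)
  if (m > n || m < 1) stop("need 1 <= m <= n", call. = FALSE)
  r <- integer(m)
  at <- switch(kind, scheme1 = 1L, scheme2 = as.integer(ceiling(m / 2)), scheme3 = m)
  r[at] <- n - m
  r
}

#' Simulate an ordinary progressive Type-II censored sample
#'
#' Draws the `m` ordered failure times of a progressively Type-II censored
#' sample from the IER distribution using the uniform-spacings algorithm:
#' with \eqn{\tau_i} iid uniform, set
#' \eqn{v_i = \tau_i^{1/(i + \sum_{j=m-i+1}^m R_j)}},
#' \eqn{U_i = 1 - v_m v_{m-1} \cdots v_{m-i+1}} and
#' \eqn{X_i = F^{-1}(U_i)}.  The \eqn{U_i} are the order statistics of a
#' progressively censored uniform sample, so the returned times are strictly
#' increasing.
#'
#' @param plan a [censoring_plan] (its `threshold` is ignored here; hybrid
#'   truncation is a separate step, see [phtics_truncate]).
#' @inheritParams ier
#' @return numeric vector of `m` increasing failure times.
#' @export
rprogressive <- function(plan, theta, lambda, seed = NULL) {
  stopifnot(inherits(plan, "censoring_plan"))
  check_params(theta, lambda)
  local_seed(seed)
  m <- plan$m
  R <- plan$removals
  tau <- stats::runif(m)
  ## gamma_i = i + R_m + ... + R_{m-i+1}: number of units still at risk
  ## "behind" position m - i + 1
  tail_sums <- cumsum(rev(R))            # sum of last i removals
  v <- tau^(1 / (seq_len(m) + tail_sums))
  u <- 1 - cumprod(rev(v))               # U_i = 1 - v_m v_{m-1} ... v_{m-i+1}
  qier(u, theta, lambda)
}

#' Assemble / truncate a progressive hybrid Type-I censored sample
#'
#' `phtics_truncate` applies the hybrid time limit of `plan` to a complete
#' progressive Type-II sample of length `m`: if the m-th failure precedes the
#' threshold the experiment ends there (Case I); otherwise it ends at the
#' threshold with only the `d` failures observed before it (Case II) and a
#' terminal removal of all remaining units.  `as_phtics` performs the same
#' bookkeeping but also accepts an already-truncated vector of `r <= m`
#' observed times, which is how printed censored datasets are entered.
#'
#' @param times increasing failure times (length `m` for `phtics_truncate`,
#'   length `r <= m` for `as_phtics`).
#' @param plan a [censoring_plan].
#' @return An object of class `phtics_sample`: a list with `times`, `r`
#'   (observed failures), `case` (`"I"` or `"II"`), `C` (termination time),
#'   `removals_applied`, `R_T` (terminal removal) and `plan`.  Unit
#'   accounting always satisfies `n = r + sum(removals_applied) + R_T`.
#' @examples
#' plan <- censoring_plan(10, 5, c(5, 0, 0, 0, 0), threshold = 2)
#' x <- rprogressive(plan, theta = 2, lambda = 1, seed = 1)
#' phtics_truncate(x, plan)
#' @export
phtics_truncate <- function(times, plan) {
  stopifnot(inherits(plan, "censoring_plan"))
  if (length(times) != plan$m) {
    stop("'times' must contain the full m progressive failure times", call. = FALSE)
  }
  as_phtics(times, plan)
}

#' @rdname phtics_truncate
#' @export
as_phtics <- function(times, plan) {
  stopifnot(inherits(plan, "censoring_plan"))
  times <- as.numeric(times)
  if (length(times) < 1 || length(times) > plan$m) {
    stop("'times' must hold between 1 and m failure times", call. = FALSE)
  }
  if (is.unsorted(times)) stop("'times' must be sorted increasing", call. = FALSE)
  check_x(times, "times")
  Tt <- plan$threshold
  if (length(times) == plan$m && times[plan$m] < Tt) {
    ## Case I: the m-th failure occurred first
    out <- list(times = times, r = plan$m, case = "I", C = times[plan$m],
                removals_applied = plan$removals, R_T = 0L, plan = plan)
  } else {
    ## Case II: the time limit hit first; keep failures strictly before T
    d <- sum(times < Tt)
    if (d == 0L) {
      stop("empty sample: no failures observed before the threshold (d = 0)",
           call. = FALSE)
    }
    times <- times[seq_len(d)]
    applied <- plan$removals[seq_len(d)]
    R_T <- plan$n - d - sum(applied)
    if (R_T < 0) stop("inconsistent plan: negative terminal removal", call. = FALSE)
    out <- list(times = times, r = d, case = "II", C = Tt,
                removals_applied = applied, R_T = as.integer(R_T), plan = plan)
  }
  structure(out, class = "phtics_sample")
}

#' @export
print.phtics_sample <- function(x, ...) {
  cat(sprintf(
    "PHT-ICS sample (Case %s): n = %d, m = %d, T = %g; r = %d observed, C = %g, R_T = %d\n",
    x$case, x$plan$n, x$plan$m, x$plan$threshold, x$r, x$C, x$R_T))
  cat("times:", format(x$times), "\n")
  invisible(x)
}

#' Generate a progressive hybrid Type-I censored sample from the IER model
#'
#' Composition of [rprogressive] and [phtics_truncate]: simulates the full
#' progressive Type-II sample under `plan` and applies the hybrid threshold.
#'
#' @inheritParams rprogressive
#' @return a `phtics_sample`, see [phtics_truncate].
#' @export
rphtics <- function(plan, theta, lambda, seed = NULL) {
  local_seed(seed)
  phtics_truncate(rprogressive(plan, theta, lambda), plan)
}

#' Read and write censored samples as plain text
#'
#' The on-disk format is line-oriented: header lines `n`, `m`, `threshold`,
#' `removals` (the m planned removals, space separated), a literal `times`
#' line, then one observed failure time per line.
#'
#' @param sample a `phtics_sample`.
#' @param path file path.
#' @return `read_phtics` returns a `phtics_sample`; `write_phtics` invisibly
#'   returns `path`.
#' @export
write_phtics <- function(sample, path) {
  stopifnot(inherits(sample, "phtics_sample"))
  p <- sample$plan
  lines <- c(sprintf("n %d", p$n), sprintf("m %d", p$m),
             sprintf("threshold %.17g", p$threshold),
             paste("removals", paste(p$removals, collapse = " ")),
             "times", sprintf("%.17g", sample$times))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phtics
#' @export
read_phtics <- function(path) {
  lines <- readLines(path)
  grab <- function(key) {
    i <- grep(paste0("^", key, "( |$)"), lines)
    if (length(i) != 1L) {
      stop(sprintf("parse error: expected exactly one '%s' line (found %d)",
                   key, length(i)), call. = FALSE)
    }
    i
  }
  num <- function(i, key) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "[[:space:]]+")[[1]][-1]))
    if (any(is.na(v))) stop(sprintf("parse error at line %d ('%s')", i, key), call. = FALSE)
    v
  }
  n <- num(grab("n"), "n"); m <- num(grab("m"), "m")
  thr <- num(grab("threshold"), "threshold")
  rem <- num(grab("removals"), "removals")
  it <- grab("times")
  body <- lines[-seq_len(it)]
  body <- body[nzchar(trimws(body))]
  times <- suppressWarnings(as.numeric(body))
  if (any(is.na(times))) {
    bad <- it + which(is.na(times))[1]
    stop(sprintf("parse error at line %d: not a number", bad), call. = FALSE)
  }
  as_phtics(times, censoring_plan(n, m, rem, thr))
}
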