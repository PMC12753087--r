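#' Monte-Carlo performance metrics
#'
#' Point-estimator metrics across replicates: `metric_ape` the average point
#' estimate, `metric_rmse` the root mean squared error
#' \eqn{\sqrt{\mathrm{mean}[(\hat\xi - \xi)^2]}}, `metric_mrab` the mean
#' relative absolute bias \eqn{\mathrm{mean}|\hat\xi - \xi| / \xi}.
#' Interval metrics: `metric_acl` the average length and `metric_cp` the
#' coverage percentage (0-100) of intervals containing the truth.
#'
#' @param estimates numeric vector of replicate point estimates.
#' @param truth true parameter value (non-zero for `metric_mrab`).
#' @param intervals two-column matrix or data frame of `(lower, upper)`
#'   bounds, one row per replicate.
#' @return scalar metric.
#' @examples
#' metric_rmse(c(0.3, 0.5), 0.4)   # 0.1
#' metric_mrab(c(0.3, 0.5), 0.4)   # 0.25
#' @export
metric_ape <- function(estimates, truth) {
  if (!length(estimates)) stop("empty estimates", call. = FALSE)
  mean(estimates)
}

#' @rdname metric_ape
#' @export
metric_rmse <- function(estimates, truth) {
  if (!length(estimates)) stop("empty estimates", call. = FALSE)
  sqrt(mean((estimates - truth)^2))
}

#' @rdname metric_ape
#' @export
metric_mrab <- function(estimates, truth) {
  if (!length(estimates)) stop("empty estimates", call. = FALSE)
  if (truth == 0) stop("MRAB undefined for truth = 0", call. = FALSE)
  mean(abs(estimates - truth)) / truth
}

#' @rdname metric_ape
#' @export
metric_acl <- function(intervals, truth) {
  intervals <- as.matrix(intervals)
  if (!nrow(intervals)) stop("empty intervals", call. = FALSE)
  mean(intervals[, 2] - intervals[, 1])
}

#' @rdname metric_ape
#' @export
metric_cp <- function(intervals, truth) {
  intervals <- as.matrix(intervals)
  if (!nrow(intervals)) stop("empty intervals", call. = FALSE)
  100 * mean(intervals[, 1] <= truth & truth <= intervals[, 2])
}
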