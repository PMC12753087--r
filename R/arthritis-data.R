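#' Arthritis relief-time data
#'
#' Relief times (hours divided by ten) of fifty arthritis patients receiving
#' a fixed dose of an analgesic, a standard benchmark dataset for inverted
#' lifetime models.  `arthritis_relief()` returns the complete sample;
#' `arthritis_phtics()` returns one of the four progressively hybrid Type-I
#' censored subsamples derived from it (all with `m = 25` planned failures
#' out of `n = 50`):
#'
#' * `S1`: removals \eqn{(1^{25})}, threshold 7.4 — Case II with 20 observed
#'   failures and terminal removal 10;
#' * `S2`: removals \eqn{(25, 0^{24})}, threshold 8.5 — Case I;
#' * `S3`: removals \eqn{(0^{12}, 25, 0^{12})}, threshold 6.9 — Case II with
#'   21 observed failures and terminal removal 4;
#' * `S4`: removals \eqn{(0^{24}, 25)}, threshold 6.1 — Case I.
#'
#' @param id one of `"S1"`, `"S2"`, `"S3"`, `"S4"`.
#' @return `arthritis_relief()` a numeric vector of length 50;
#'   `arthritis_phtics()` a `phtics_sample`.
#' @examples
#' fit_ier(arthritis_phtics("S1"), x0 = 5)
#' @export
arthritis_relief <- function() {
  c(2.9, 2.9, 3.4, 3.4, 3.5, 3.6, 3.6, 3.6, 4.4, 4.4,
    4.6, 4.6, 4.9, 4.9, 5.0, 5.0, 5.2, 5.4, 5.5, 5.5,
    5.5, 5.6, 5.7, 5.8, 5.9, 5.9, 6.0, 6.0, 6.1, 6.1,
    6.2, 6.4, 6.8, 7.0, 7.0, 7.1, 7.1, 7.1, 7.2, 7.3,
    7.5, 7.5, 8.0, 8.0, 8.1, 8.2, 8.4, 8.4, 8.4, 8.7)
}

#' @rdname arthritis_relief
#' @export
arthritis_phtics <- function(id = c("S1", "S2", "S3", "S4")) {
  id <- match.arg(id)
  spec <- switch(id,
    S1 = list(removals = rep(1L, 25), threshold = 7.4,
              times = c(2.9, 3.4, 3.5, 3.6, 4.4, 4.6, 4.9, 5.0, 5.2, 5.5,
                        5.5, 5.7, 5.9, 6.0, 6.1, 6.2, 6.8, 7.0, 7.1, 7.2)),
    S2 = list(removals = c(25L, rep(0L, 24)), threshold = 8.5,
              times = c(2.9, 3.4, 3.5, 3.6, 4.4, 4.6, 4.9, 5.0, 5.5, 5.7,
                        5.8, 5.9, 6.0, 6.0, 6.1, 6.2, 6.4, 6.8, 7.1, 7.2,
                        7.3, 7.5, 7.5, 8.0, 8.1)),
    S3 = list(removals = c(rep(0L, 12), 25L, rep(0L, 12)), threshold = 6.9,
              times = c(2.9, 2.9, 3.4, 3.4, 3.5, 3.6, 3.6, 3.6, 4.4, 4.4,
                        4.6, 4.6, 4.9, 4.9, 5.0, 5.4, 5.5, 5.5, 5.7, 6.1,
                        6.8)),
    S4 = list(removals = c(rep(0L, 24), 25L), threshold = 6.1,
              times = c(2.9, 2.9, 3.4, 3.4, 3.5, 3.6, 3.6, 3.6, 4.4, 4.4,
                        4.6, 4.6, 4.9, 4.9, 5.0, 5.0, 5.2, 5.4, 5.5, 5.5,
                        5.5, 5.6, 5.7, 5.8, 5.9)))
  as_phtics(spec$times, censoring_plan(50, 25, spec$removals, spec$threshold))
}
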