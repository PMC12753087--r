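## Auxiliary quantities shared by the MPS objective, gradient and Hessian.
## Index 1..r holds the observed failures; "aug" vectors carry the boundary
## conventions F(x_0) = 0 (survival 1) and F(x_{r+1}) = 1 (survival 0).
mps_parts <- function(theta, lambda, sample) {
  u <- unpack_sample(sample)
  x <- u$x; r <- u$r
  xi2 <- 1 / x^2
  y <- lambda * xi2
  lw <- log1mexp(y)                     # log w_i
  S <- exp(theta * lw)                  # w_i^theta (survival)
  D <- S * lw                           # d S / d theta
  E <- S * lw^2
  phi <- xi2 * exp(-y + (theta - 1) * lw)   # (1/theta) d S / d lambda
  rho <- xi2 * exp(-y - lw)             # x^-2 e^-y / w
  dphi <- xi2 * phi * ((theta - 1) * exp(-y - lw) - 1)  # d phi / d lambda
  dD <- phi * (theta * lw + 1)          # d D / d lambda
  aug <- function(v) c(0, v, 0)         # boundary contributions vanish
  ## spacings Delta_i = S_{i-1} - S_i, i = 1..r+1, evaluated stably from the
  ## log survivals
  lwa <- c(0, theta * lw, -Inf)         # log survival, augmented
  Delta <- exp(lwa[1:(r + 1)]) * (-expm1(pmin(lwa[2:(r + 2)] - lwa[1:(r + 1)], 0)))
  Delta[r + 1] <- S[r]
  ## interior ties (x_{i-1} == x_i) give a zero spacing; flag them for the
  ## density substitution
  tied <- c(FALSE, diff(x) <= 0, FALSE)
  yC <- lambda / u$C^2
  lwC <- log1mexp(yC)
  rhoC <- (1 / u$C^2) * exp(-yC - lwC)
  list(x = x, r = r, R = u$R, R_T = u$R_T, C = u$C,
       xi2 = xi2, y = y, lw = lw, S = S,
       Saug = c(1, S, 0),
       Daug = aug(D), Eaug = aug(E), phiaug = aug(phi),
       dphiaug = aug(dphi), dDaug = aug(dD),
       rho = rho, drho = -rho * (xi2 + rho),
       Delta = Delta, tied = tied,
       lwC = lwC, rhoC = rhoC,
       drhoC = -rhoC * (1 / u$C^2 + rhoC))
}

#' Maximum-product-of-spacings objective for PHT-ICS data
#'
#' The log product-of-spacings criterion augments the usual sum of log CDF
#' increments between consecutive ordered failures (with the conventions
#' \eqn{F(x_0) = 0}, \eqn{F(x_{r+1}) = 1}) by survival-power terms for the
#' progressively removed units and the terminal removal:
#' \deqn{s(\theta,\lambda) = \sum_{i=1}^{r+1} \log[w_{i-1}^\theta - w_i^\theta]
#'   + \theta \sum_{i=1}^r R_i \log w_i + \theta R_T \log w_C,}
#' where \eqn{w_i = 1 - e^{-\lambda x_i^{-2}}}.  A tied pair of observations
#' would make its spacing exactly zero; following the usual remedy for
#' continuous models observed on a rounded scale, a zero spacing is replaced
#' by the density \eqn{f(x_i)} so the objective stays finite (and the
#' gradient/Hessian use the corresponding log-density derivatives).
#'
#' `ier_mps_gradient` is the analytic gradient, `ier_mps_info` the negated
#' analytic Hessian used for MPS-based asymptotic confidence intervals.
#'
#' @inheritParams ier_loglik
#' @return scalar objective, length-2 gradient, or 2x2 information matrix.
#' @seealso [fit_ier] with `method = "mps"`.
#' @export
ier_mps_objective <- function(theta, lambda, sample) {
  check_params(theta, lambda)
  p <- mps_parts(theta, lambda, sample)
  lsp <- log(p$Delta)
  if (any(p$tied)) {
    i <- which(p$tied)                  # spacing i spans x_{i-1} = x_i
    xi <- p$x[i]                        # (i here indexes spacings 1..r+1)
    lsp[i] <- dier(xi, theta, lambda, log = TRUE)
  }
  sum(lsp) + theta * sum(p$R * p$lw) + theta * p$R_T * p$lwC
}

#' @rdname ier_mps_objective
#' @export
ier_mps_gradient <- function(theta, lambda, sample) {
  check_params(theta, lambda)
  p <- mps_parts(theta, lambda, sample)
  r1 <- p$r + 1
  i0 <- 1:r1; i1 <- 2:(r1 + 1)
  gD <- (p$Daug[i0] - p$Daug[i1]) / p$Delta
  gphi <- theta * (p$phiaug[i0] - p$phiaug[i1]) / p$Delta
  if (any(p$tied)) {
    j <- which(p$tied)
    xi <- p$x[j]; lwj <- p$lw[j]; rhoj <- p$rho[j]
    gD[j] <- 1 / theta + lwj
    gphi[j] <- 1 / lambda - 1 / xi^2 + (theta - 1) * rhoj
  }
  c(dtheta = sum(gD) + sum(p$R * p$lw) + p$R_T * p$lwC,
    dlambda = sum(gphi) + theta * (sum(p$R * p$rho) + p$R_T * p$rhoC))
}

#' @rdname ier_mps_objective
#' @export
ier_mps_info <- function(theta, lambda, sample) {
  check_params(theta, lambda)
  p <- mps_parts(theta, lambda, sample)
  r1 <- p$r + 1
  i0 <- 1:r1; i1 <- 2:(r1 + 1)
  dD <- p$Daug[i0] - p$Daug[i1]
  dE <- p$Eaug[i0] - p$Eaug[i1]
  g <- p$phiaug[i0] - p$phiaug[i1]
  dk <- p$dphiaug[i0] - p$dphiaug[i1]
  ddD <- p$dDaug[i0] - p$dDaug[i1]
  htt <- dE / p$Delta - (dD / p$Delta)^2
  hll <- theta * dk / p$Delta - theta^2 * g^2 / p$Delta^2
  htl <- ddD / p$Delta - theta * g * dD / p$Delta^2
  if (any(p$tied)) {
    j <- which(p$tied)
    xi <- p$x[j]; rhoj <- p$rho[j]
    drhoj <- -(1 / xi^2) * rhoj * (1 + rhoj * xi^2)
    htt[j] <- -1 / theta^2
    hll[j] <- -1 / lambda^2 + (theta - 1) * drhoj
    htl[j] <- rhoj
  }
  d2_tt <- sum(htt)
  d2_ll <- sum(hll) + theta * (sum(p$R * p$drho) + p$R_T * p$drhoC)
  d2_tl <- sum(htl) + sum(p$R * p$rho) + p$R_T * p$rhoC
  -matrix(c(d2_tt, d2_tl, d2_tl, d2_ll), 2, 2,
          dimnames = list(c("theta", "lambda"), c("theta", "lambda")))
}
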