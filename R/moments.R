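#' Moments, entropy, skewness and kurtosis of the W-TEXPD
#'
#' With `Z = (X - tau)/lambda` standard Weibull (`E Z^k = Gamma(k/beta + 1)`),
#' the raw moments follow from the binomial expansion of `(tau + lambda*Z)^r`;
#' the central moments are computed from them by the usual identities and are
#' free of `tau`, so skewness and kurtosis depend on the shape `beta` only.
#'
#' @inheritParams wtexpd-distribution
#' @param r moment order, an integer in 1..4.
#' @return A single numeric value.
#' @examples
#' wtexpd_mean(tau = 2, alpha = 3, theta = 1, beta = 1)      # 5
#' wtexpd_skewness(beta = 1)                                  # 2
#' @name wtexpd-moments
NULL

# E Z^k for Z standard Weibull(shape beta)
weibull_gk <- function(k, beta) gamma(k / beta + 1)

#' @rdname wtexpd-moments
#' @export
wtexpd_raw_moment <- function(r, tau = 0, alpha = 1, theta = 1, beta = 1) {
  check_wtexpd_params(tau, alpha, theta, beta)
  if (length(r) != 1L || !(r %in% 1:4))
    stop("'r' must be an integer between 1 and 4", call. = FALSE)
  lam <- alpha / theta
  k <- 0:r
  sum(choose(r, k) * tau^(r - k) * lam^k * vapply(k, weibull_gk, 0, beta = beta))
}

#' @rdname wtexpd-moments
#' @export
wtexpd_mean <- function(tau = 0, alpha = 1, theta = 1, beta = 1) {
  check_wtexpd_params(tau, alpha, theta, beta)
  tau + (alpha / theta) * gamma(1 / beta + 1)
}

#' @rdname wtexpd-moments
#' @export
wtexpd_variance <- function(tau = 0, alpha = 1, theta = 1, beta = 1) {
  check_wtexpd_params(tau, alpha, theta, beta)
  (alpha / theta)^2 * (gamma(2 / beta + 1) - gamma(1 / beta + 1)^2)
}

# standardized central moments via E(X - EX)^r = sum_k C(r,k) E X^k (-EX)^(r-k);
# tau and lambda cancel, so work with the standard Weibull moments directly
wtexpd_std_moment <- function(r, beta) {
  g <- vapply(1:4, weibull_gk, 0, beta = beta)
  m2 <- g[2] - g[1]^2
  if (r == 3) {
    (g[3] - 3 * g[1] * g[2] + 2 * g[1]^3) / m2^1.5
  } else {
    (g[4] - 4 * g[1] * g[3] + 6 * g[1]^2 * g[2] - 3 * g[1]^4) / m2^2
  }
}

#' @rdname wtexpd-moments
#' @export
wtexpd_skewness <- function(tau = 0, alpha = 1, theta = 1, beta = 1) {
  check_wtexpd_params(tau, alpha, theta, beta)
  wtexpd_std_moment(3, beta)
}

#' @rdname wtexpd-moments
#' @export
wtexpd_kurtosis <- function(tau = 0, alpha = 1, theta = 1, beta = 1) {
  check_wtexpd_params(tau, alpha, theta, beta)
  wtexpd_std_moment(4, beta)
}

#' Shannon entropy of the W-TEXPD
#'
#' Closed form
#' \deqn{\eta = 1 + \frac{\beta-1}{\beta}\{C + \beta\ln(\theta/\alpha)\}
#'       - \ln\{\beta(\theta/\alpha)^\beta\},}
#' with `C` the Euler-Mascheroni constant; equivalently the Weibull entropy
#' `C(1 - 1/beta) + ln(lambda/beta) + 1`.  Invariant to the location `tau`.
#'
#' @inheritParams wtexpd-distribution
#' @return The differential entropy in nats.
#' @examples
#' wtexpd_entropy(beta = 1, alpha = 1, theta = 1)  # 1, the unit exponential
#' @export
wtexpd_entropy <- function(tau = 0, alpha = 1, theta = 1, beta = 1) {
  check_wtexpd_params(tau, alpha, theta, beta)
  inv_lam <- theta / alpha
  1 + (beta - 1) / beta * (euler_gamma + beta * log(inv_lam)) -
    log(beta * inv_lam^beta)
}
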