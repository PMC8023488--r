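#' The Weibull-truncated exponential distribution (W-TEXPD)
#'
#' Density, distribution function, survival function, quantile function,
#' hazard, cumulative hazard and random generation for the W-TEXPD with
#' location `tau`, shape `beta` and scale components `alpha`, `theta`
#' (identifiable only through `lambda = alpha/theta`):
#' \deqn{g(x) = \frac{\beta}{\lambda^\beta}(x-\tau)^{\beta-1}
#'       e^{-\{(x-\tau)/\lambda\}^\beta}, \qquad x > \tau.}
#'
#' Special cases: `tau = 0, theta = 1, beta = 1` gives the exponential
#' distribution with rate `1/alpha`; `theta = 1` gives the three-parameter
#' Weibull with threshold `tau`, shape `beta`, scale `alpha`.
#'
#' At the boundary `x = tau` the density is returned as its limit: `0` for
#' `beta > 1`, `1/lambda` for `beta = 1`, and `Inf` (with a warning) for
#' `beta < 1`, where the density diverges.
#'
#' @param x,q vector of quantiles.
#' @param p vector of probabilities in `[0, 1)` for `qwtexpd`.
#' @param n number of draws.
#' @param tau location/threshold parameter.
#' @param alpha,theta scale components; only `alpha/theta > 0` matters.
#' @param beta shape parameter, `> 0`.
#' @param log,log.p logical; if `TRUE`, probabilities/densities are on the
#'   log scale.
#' @param lower.tail logical; if `TRUE` (default) probabilities are
#'   `P(X <= x)`, otherwise `P(X > x)`.
#'
#' @return `dwtexpd` the density, `pwtexpd` the cdf, `swtexpd` the survival
#'   function, `qwtexpd` the quantile function, `hwtexpd` the hazard,
#'   `chwtexpd` the cumulative hazard, `rwtexpd` a vector of draws.
#' @examples
#' dwtexpd(1, tau = 0, alpha = 1, theta = 1, beta = 1)  # exp(-1)
#' qwtexpd(0.5, tau = 2, alpha = 3, theta = 1, beta = 2)
#' @name wtexpd-distribution
NULL

#' @rdname wtexpd-distribution
#' @export
dwtexpd <- function(x, tau = 0, alpha = 1, theta = 1, beta = 1, log = FALSE) {
  check_wtexpd_params(tau, alpha, theta, beta)
  lam <- alpha / theta
  d <- numeric(length(x))
  d[x < tau] <- 0
  at <- which(x == tau)
  if (length(at)) {
    if (beta < 1) {
      warning("density diverges at the support boundary x = tau for beta < 1")
      d[at] <- Inf
    } else {
      d[at] <- if (beta == 1) 1 / lam else 0
    }
  }
  above <- which(x > tau)
  if (length(above)) {
    z <- (x[above] - tau) / lam
    d[above] <- exp(log(beta / lam) + (beta - 1) * log(z) - z^beta)
  }
  if (log) log(d) else d
}

#' @rdname wtexpd-distribution
#' @export
pwtexpd <- function(q, tau = 0, alpha = 1, theta = 1, beta = 1,
                    lower.tail = TRUE, log.p = FALSE) {
  check_wtexpd_params(tau, alpha, theta, beta)
  lam <- alpha / theta
  z <- pmax(q - tau, 0) / lam
  if (lower.tail) {
    pr <- -expm1(-z^beta)
    if (log.p) log(pr) else pr
  } else {
    if (log.p) -z^beta else exp(-z^beta)
  }
}

#' @rdname wtexpd-distribution
#' @export
swtexpd <- function(q, tau = 0, alpha = 1, theta = 1, beta = 1) {
  pwtexpd(q, tau, alpha, theta, beta, lower.tail = FALSE)
}

#' @rdname wtexpd-distribution
#' @export
qwtexpd <- function(p, tau = 0, alpha = 1, theta = 1, beta = 1,
                    lower.tail = TRUE, log.p = FALSE) {
  check_wtexpd_params(tau, alpha, theta, beta)
  if (log.p) p <- exp(p)
  if (!lower.tail) p <- 1 - p
  if (any(p < 0 | p >= 1))
    stop("probabilities must lie in [0, 1)", call. = FALSE)
  lam <- alpha / theta
  tau + lam * (-log1p(-p))^(1 / beta)
}

#' @rdname wtexpd-distribution
#' @export
rwtexpd <- function(n, tau = 0, alpha = 1, theta = 1, beta = 1) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  qwtexpd(stats::runif(n), tau, alpha, theta, beta)
}

#' @rdname wtexpd-distribution
#' @param t vector of times, `> tau` for `hwtexpd`, `>= tau` for `chwtexpd`.
#' @export
hwtexpd <- function(t, tau = 0, alpha = 1, theta = 1, beta = 1) {
  check_wtexpd_params(tau, alpha, theta, beta)
  if (any(t <= tau))
    stop("hazard is defined only above the threshold: need t > tau",
         call. = FALSE)
  lam <- alpha / theta
  beta * (1 / lam)^beta * (t - tau)^(beta - 1)
}

#' @rdname wtexpd-distribution
#' @export
chwtexpd <- function(t, tau = 0, alpha = 1, theta = 1, beta = 1) {
  check_wtexpd_params(tau, alpha, theta, beta)
  if (any(t < tau))
    stop("cumulative hazard is defined on t >= tau", call. = FALSE)
  ((t - tau) / (alpha / theta))^beta
}

#' Density of an order statistic of a W-TEXPD sample
#'
#' Density of the r-th smallest value in an iid sample of size `n`:
#' \deqn{f_{r:n}(x) = \frac{n!}{(r-1)!\,(n-r)!}\,
#'       g(x)\,G(x)^{r-1}\,\{1 - G(x)\}^{n-r}.}
#'
#' @inheritParams wtexpd-distribution
#' @param r rank of the order statistic, `1 <= r <= n`.
#' @param n sample size.
#' @return Density values of the r-th order statistic at `x`.
#' @examples
#' # minimum of 5 unit exponentials is Exponential(rate 5)
#' dwtexpd_order(0.2, r = 1, n = 5)
#' @export
dwtexpd_order <- function(x, r, n, tau = 0, alpha = 1, theta = 1, beta = 1) {
  if (length(r) != 1L || length(n) != 1L || r != round(r) || n != round(n) ||
      r < 1 || r > n)
    stop("need integer ranks with 1 <= r <= n", call. = FALSE)
  cn <- exp(lgamma(n + 1) - lgamma(r) - lgamma(n - r + 1))
  g <- dwtexpd(x, tau, alpha, theta, beta)
  G <- pwtexpd(x, tau, alpha, theta, beta)
  cn * g * G^(r - 1) * (1 - G)^(n - r)
}
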