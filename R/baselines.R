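#' Baseline lifetime models: Exponential, truncated Exponential, Weibull, Gamma
#'
#' Closed-form or profile-equation maximum-likelihood fits of the four
#' comparison models.  The exponential rate MLE is `1/mean(x)`; the
#' left-truncated exponential (TEXPD) with known threshold `tau` has density
#' `theta * exp(-theta*(x - tau))` and rate MLE `1/(mean(x) - tau)`; the
#' Weibull shape solves the standard profile equation by safeguarded Newton
#' iteration; the Gamma shape solves the digamma profile equation
#' `log(shape) - digamma(shape) = log(mean(x)) - mean(log(x))`.
#'
#' @param x numeric vector of observations (positive; `> tau` for the
#'   truncated exponential).
#' @param tau known truncation threshold for `fit_texpd`, strictly below
#'   `min(x)`.
#' @return A `"wtexpd_fit"` object (see [fit_wtexpd()]).
#' @examples
#' fit_exponential(wtexpd_data("ball_bearings")$values)
#' @name baseline-fits
NULL

#' @rdname baseline-fits
#' @export
fit_exponential <- function(x) {
  x <- as_sample_values(x)
  if (any(x <= 0)) stop("exponential fit needs positive data", call. = FALSE)
  n <- length(x)
  rate <- 1 / mean(x)
  se <- rate / sqrt(n)
  new_wtexpd_fit("Exponential", c(rate = rate), c(rate = se),
                 matrix(se^2, dimnames = list("rate", "rate")),
                 loglik = n * (log(rate) - 1), k = 1, n = n)
}

#' @rdname baseline-fits
#' @export
fit_texpd <- function(x, tau = 0) {
  x <- as_sample_values(x)
  check_support(x, tau)
  n <- length(x)
  rate <- 1 / (mean(x) - tau)
  se <- rate / sqrt(n)
  new_wtexpd_fit("TEXPD", c(tau = tau, rate = rate), c(tau = 0, rate = se),
                 matrix(se^2, dimnames = list("rate", "rate")),
                 loglik = n * (log(rate) - 1), k = 1, n = n,
                 tau = tau, tau_fixed = TRUE)
}

#' @rdname baseline-fits
#' @export
fit_weibull <- function(x) {
  x <- as_sample_values(x)
  if (any(x <= 0)) stop("Weibull fit needs positive data", call. = FALSE)
  n <- length(x)
  lx <- log(x)
  g <- function(k) 1 / k + mean(lx) - sum(x^k * lx) / sum(x^k)
  gp <- function(k) {
    xk <- x^k; sw <- sum(xk)
    -1 / k^2 - (sum(xk * lx^2) * sw - sum(xk * lx)^2) / sw^2
  }
  k <- 1
  converged <- FALSE
  for (iter in 1:200) {
    gk <- g(k)
    if (abs(gk) < 1e-10) { converged <- TRUE; break }
    step <- -gk / gp(k)
    newk <- k + step
    halvings <- 0L
    while ((newk <= 0 || abs(g(newk)) > abs(gk)) && halvings < 50L) {
      step <- step / 2; newk <- k + step; halvings <- halvings + 1L
    }
    if (newk <= 0) break
    k <- newk
  }
  scale <- mean(x^k)^(1 / k)
  ll <- sum(stats::dweibull(x, k, scale, log = TRUE))
  vc <- mle2_vcov(function(p) -sum(stats::dweibull(x, p[1], p[2], log = TRUE)),
                  c(k, scale), c("shape", "scale"))
  new_wtexpd_fit("Weibull", c(shape = k, scale = scale),
                 sqrt(pmax(diag(vc), 0)), vc, ll, k = 2, n = n,
                 converged = converged, iterations = iter)
}

#' @rdname baseline-fits
#' @export
fit_gamma <- function(x) {
  x <- as_sample_values(x)
  if (any(x <= 0)) stop("Gamma fit needs positive data", call. = FALSE)
  n <- length(x)
  s <- log(mean(x)) - mean(log(x))
  # digamma profile equation log(a) - digamma(a) = s, Newton from the
  # standard starting value
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  converged <- FALSE
  for (iter in 1:200) {
    f <- log(a) - digamma(a) - s
    if (abs(f) < 1e-12) { converged <- TRUE; break }
    a <- a - f / (1 / a - trigamma(a))
    if (a <= 0) break
  }
  rate <- a / mean(x)
  ll <- sum(stats::dgamma(x, a, rate, log = TRUE))
  vc <- mle2_vcov(function(p) -sum(stats::dgamma(x, p[1], p[2], log = TRUE)),
                  c(a, rate), c("shape", "rate"))
  new_wtexpd_fit("Gamma", c(shape = a, rate = rate),
                 sqrt(pmax(diag(vc), 0)), vc, ll, k = 2, n = n,
                 converged = converged, iterations = iter)
}

# covariance from the numeric Hessian of a 2-parameter negative log-likelihood
mle2_vcov <- function(nll, par, nm) {
  h <- matrix(NA_real_, 2, 2)
  eps <- pmax(abs(par), 1) * 1e-4
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0); ei[i] <- eps[i]; ej[j] <- eps[j]
    h[i, j] <- (nll(par + ei + ej) - nll(par + ei - ej) -
                nll(par - ei + ej) + nll(par - ei - ej)) / (4 * eps[i] * eps[j])
  }
  out <- tryCatch(solve((h + t(h)) / 2), error = function(e) matrix(NA_real_, 2, 2))
  dimnames(out) <- list(nm, nm)
  out
}

#' Cumulative distribution function of a fitted model
#'
#' Returns the fitted cdf evaluated at `x`, for use in goodness-of-fit
#' statistics and probability plots.
#'
#' @param fit a `"wtexpd_fit"` from any of the fitting functions.
#' @param x vector of quantiles.
#' @return Probabilities `F(x)` under the fitted model.
#' @export
model_cdf <- function(fit, x) {
  if (!inherits(fit, "wtexpd_fit")) stop("'fit' must be a wtexpd_fit")
  p <- fit$params
  switch(fit$model,
    "W-TEXPD" = pwtexpd(x, p[["tau"]], p[["lambda"]], 1, p[["beta"]]),
    "Weibull" = stats::pweibull(x, p[["shape"]], p[["scale"]]),
    "Gamma" = stats::pgamma(x, p[["shape"]], p[["rate"]]),
    "Exponential" = stats::pexp(x, p[["rate"]]),
    "TEXPD" = ifelse(x <= p[["tau"]], 0,
                     -expm1(-p[["rate"]] * (x - p[["tau"]]))),
    stop(sprintf("unknown model '%s'", fit$model), call. = FALSE)
  )
}
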