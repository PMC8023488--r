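#' Parameter set of the Weibull-truncated exponential distribution
#'
#' The W-TEXPD has four parameters: a location (threshold) `tau`, a shape
#' `beta > 0`, and two scale components `alpha` and `theta` that enter the
#' distribution only through their ratio `lambda = alpha/theta > 0`.  The
#' pair (`alpha`, `theta`) is therefore not jointly identifiable: any common
#' rescaling (`c*alpha`, `c*theta`) leaves the distribution unchanged, and
#' both components may individually be negative as long as the ratio is
#' positive.
#'
#' @param tau location/threshold; the support is `(tau, Inf)`.
#' @param alpha scale numerator (any nonzero real).
#' @param theta scale denominator (same sign as `alpha`).
#' @param beta shape, `> 0`.
#'
#' @return An object of class `"wtexpd_params"`: a list with fields
#'   `tau`, `alpha`, `theta`, `beta` and the derived identifiable scale
#'   `lambda = alpha/theta`.
#' @examples
#' p <- wtexpd_params(tau = 16.25, alpha = 1.18, theta = 0.02, beta = 1.52)
#' p$lambda
#' @export
wtexpd_params <- function(tau = 0, alpha = 1, theta = 1, beta = 1) {
  check_wtexpd_params(tau, alpha, theta, beta)
  structure(
    list(tau = tau, alpha = alpha, theta = theta, beta = beta,
         lambda = alpha / theta),
    class = "wtexpd_params"
  )
}

# shared validation for all analytic functions; lambda = alpha/theta must be
# positive even when alpha and theta are individually negative
check_wtexpd_params <- function(tau, alpha, theta, beta) {
  if (!all(is.finite(c(tau, alpha, theta, beta))))
    stop("W-TEXPD parameters must be finite", call. = FALSE)
  if (any(beta <= 0))
    stop("shape 'beta' must be positive", call. = FALSE)
  if (any(theta == 0))
    stop("'theta' must be nonzero", call. = FALSE)
  if (any(alpha / theta <= 0))
    stop("scale ratio lambda = alpha/theta must be positive", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.wtexpd_params <- function(x, ...) {
  cat("W-TEXPD parameters\n")
  cat(sprintf("  tau = %g, alpha = %g, theta = %g, beta = %g  (lambda = alpha/theta = %g)\n",
              x$tau, x$alpha, x$theta, x$beta, x$lambda))
  invisible(x)
}

# Euler-Mascheroni constant, fixed to 15 significant digits
euler_gamma <- 0.577215664901533
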