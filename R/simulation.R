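#' Bias and mean squared error of a vector of estimates
#'
#' `mc_bias` is the mean estimate minus the truth.  `mc_mse` is the
#' variance of the estimates plus the squared bias, with the variance
#' divisor equal to the number of replications (not `reps - 1`), so that
#' `mse = mean((est - truth)^2)` exactly and `mse >= bias^2` always.
#'
#' @param estimates nonempty numeric vector of per-replication estimates.
#' @param truth the true parameter value.
#' @return A single number.
#' @examples
#' mc_bias(c(1, 3), 2)  # 0
#' mc_mse(c(1, 3), 2)   # 1
#' @export
mc_bias <- function(estimates, truth) {
  if (!length(estimates)) stop("empty estimate vector", call. = FALSE)
  mean(estimates) - truth
}

#' @rdname mc_bias
#' @export
mc_mse <- function(estimates, truth) {
  if (!length(estimates)) stop("empty estimate vector", call. = FALSE)
  mean((estimates - truth)^2)
}

#' Monte-Carlo study of the W-TEXPD maximum-likelihood estimators
#'
#' For each sample size, draws `reps` samples from the W-TEXPD by
#' inverse-transform sampling, refits by [fit_wtexpd()] with the threshold
#' known and `theta` pinned at its true value, and aggregates the mean
#' estimate, its Monte-Carlo standard error, bias and MSE for each free
#' parameter (`lambda`, `beta`).  Replications whose fit fails to converge
#' are excluded and counted.  Given the same `seed` the table is
#' reproducible bit-for-bit.
#'
#' @param lambda,beta,tau true parameter values of the generator.
#' @param n vector of sample sizes.
#' @param reps number of Monte-Carlo replications per sample size.
#' @param seed integer RNG seed.
#' @param theta_pin value at which `theta` is pinned (the true `theta`);
#'   `alpha = lambda * theta_pin`.
#' @return A `"wtexpd_sim_table"`: data frame with columns `param`, `n`,
#'   `mean_est`, `se`, `bias`, `mse`, `fail_rate`.
#' @examples
#' wtexpd_sim_study(lambda = 2, beta = 1.5, n = c(20, 50), reps = 25, seed = 1)
#' @export
wtexpd_sim_study <- function(lambda = 2, beta = 1.5, tau = 0,
                             n = c(20, 50, 100, 200), reps = 1000,
                             seed = 1, theta_pin = 1) {
  if (reps < 1) stop("'reps' must be >= 1", call. = FALSE)
  if (any(n < 5)) stop("sample sizes must be >= 5", call. = FALSE)
  set.seed(seed)
  rows <- list()
  for (nn in n) {
    est <- matrix(NA_real_, reps, 2, dimnames = list(NULL, c("lambda", "beta")))
    fails <- 0L
    for (r in seq_len(reps)) {
      x <- rwtexpd(nn, tau = tau, alpha = lambda, theta = 1, beta = beta)
      fit <- tryCatch(fit_wtexpd(x, tau = tau, theta_pin = theta_pin),
                      error = function(e) NULL)
      if (is.null(fit) || !fit$converged) { fails <- fails + 1L; next }
      est[r, ] <- fit$params[c("lambda", "beta")]
    }
    ok <- stats::complete.cases(est)
    truth <- c(lambda = lambda, beta = beta)
    for (pm in colnames(est)) {
      e <- est[ok, pm]
      rows[[length(rows) + 1L]] <- data.frame(
        param = pm, n = nn,
        mean_est = mean(e),
        se = stats::sd(e) / sqrt(length(e)),
        bias = mc_bias(e, truth[[pm]]),
        mse = mc_mse(e, truth[[pm]]),
        fail_rate = fails / reps
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "design") <- list(lambda = lambda, beta = beta, tau = tau,
                              n = n, reps = reps, seed = seed,
                              theta_pin = theta_pin)
  class(out) <- c("wtexpd_sim_table", "data.frame")
  out
}

#' @export
print.wtexpd_sim_table <- function(x, digits = 4, ...) {
  d <- attr(x, "design")
  cat(sprintf(
    "Monte-Carlo study: truth lambda = %g, beta = %g, tau = %g; %d reps, seed %d\n",
    d$lambda, d$beta, d$tau, d$reps, d$seed))
  print.data.frame(round_df(as.data.frame(x), digits), row.names = FALSE)
  invisible(x)
}

round_df <- function(d, digits) {
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], round, digits)
  d
}
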