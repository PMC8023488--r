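#' Empirical-distribution goodness-of-fit statistics
#'
#' Kolmogorov-Smirnov, Cramer-von Mises and Anderson-Darling discrepancies
#' between the empirical cdf of a sample and a fitted cdf, with the fitted
#' (estimated) parameters plugged in.  No p-values are attached: with
#' estimated parameters the usual null tables do not apply, so the bare
#' statistics are reported for model ranking only.
#'
#' For the sorted sample `x_(1) <= ... <= x_(n)` and `u_i = F(x_(i))`:
#' \deqn{D = \max_i \max\{i/n - u_i,\; u_i - (i-1)/n\}}
#' \deqn{W^2 = \frac{1}{12n} + \sum_i \{u_i - (2i-1)/(2n)\}^2}
#' \deqn{A^2 = -n - \frac{1}{n}\sum_i (2i-1)\{\ln u_i + \ln(1-u_{n+1-i})\}}
#'
#' @param x numeric sample.
#' @param cdf_fn a vectorized cdf, e.g. `function(q) model_cdf(fit, q)`.
#' @return `ks_statistic`, `cvm_statistic`, `ad_statistic` return a single
#'   number; `gof_stats` returns a named list with elements `ks`, `cvm`,
#'   `ad`.
#' @examples
#' x <- wtexpd_data("ball_bearings")$values
#' fit <- fit_exponential(x)
#' ks_statistic(x, function(q) model_cdf(fit, q))
#' @name gof-statistics
NULL

gof_u <- function(x, cdf_fn) {
  u <- cdf_fn(sort(as_sample_values(x)))
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1))
    stop("cdf_fn must return probabilities in [0, 1]", call. = FALSE)
  u
}

#' @rdname gof-statistics
#' @export
ks_statistic <- function(x, cdf_fn) {
  u <- gof_u(x, cdf_fn)
  n <- length(u)
  i <- seq_len(n)
  max(pmax(i / n - u, u - (i - 1) / n))
}

#' @rdname gof-statistics
#' @export
cvm_statistic <- function(x, cdf_fn) {
  u <- gof_u(x, cdf_fn)
  n <- length(u)
  1 / (12 * n) + sum((u - (2 * seq_len(n) - 1) / (2 * n))^2)
}

#' @rdname gof-statistics
#' @export
ad_statistic <- function(x, cdf_fn) {
  u <- gof_u(x, cdf_fn)
  n <- length(u)
  if (any(u <= 0) || any(u >= 1))
    stop(paste("Anderson-Darling needs fitted cdf values strictly inside (0, 1);",
               "use a threshold strictly below the sample minimum"),
         call. = FALSE)
  i <- seq_len(n)
  -n - sum((2 * i - 1) * (log(u) + log(1 - u[n + 1 - i]))) / n
}

#' @rdname gof-statistics
#' @export
gof_stats <- function(x, cdf_fn) {
  list(ks = ks_statistic(x, cdf_fn),
       cvm = cvm_statistic(x, cdf_fn),
       ad = ad_statistic(x, cdf_fn))
}

#' Information criteria of a fitted model
#'
#' `aic = 2k - 2*loglik`, `bic = k*log(n) - 2*loglik` with `k` the number of
#' free parameters (3 for the W-TEXPD, its threshold being fixed, not
#' estimated, during optimization).
#'
#' @param fit a `"wtexpd_fit"`.
#' @return A single number.
#' @export
aic <- function(fit) 2 * fit$k - 2 * fit$loglik

#' @rdname aic
#' @export
bic <- function(fit) fit$k * log(fit$n) - 2 * fit$loglik

#' Compare the W-TEXPD with the four baseline models on one sample
#'
#' Fits the W-TEXPD, Weibull, Gamma, Exponential and truncated-Exponential
#' models, computes AIC/BIC and the three goodness-of-fit statistics for
#' each, and ranks the models by AIC (ties broken by BIC, then label).  A
#' model whose fit fails is kept as a row of `NA`s so the report always has
#' five rows.
#'
#' @param x numeric sample (or a `"wtexpd_sample"`).
#' @param tau threshold for the W-TEXPD and truncated-Exponential fits;
#'   `NULL` for the defaults (`min(x) - 0.001*range` and `min(x)`
#'   respectively).
#' @param theta_pin passed to [fit_wtexpd()].
#' @return A `"wtexpd_comparison"`: list with the per-model `fits`, `gof`
#'   statistics, and a `table` data frame ordered by rank.
#' @examples
#' compare_models(wtexpd_data("ball_bearings"), tau = 16.25)
#' @export
compare_models <- function(x, tau = NULL, theta_pin = 1) {
  name <- if (inherits(x, "wtexpd_sample")) x$name else deparse(substitute(x))
  x <- as_sample_values(x)
  tau_te <- if (is.null(tau)) min(x) else tau
  fitters <- list(
    "W-TEXPD" = function() fit_wtexpd(x, tau = tau, theta_pin = theta_pin),
    "Weibull" = function() fit_weibull(x),
    "Gamma" = function() fit_gamma(x),
    "Exponential" = function() fit_exponential(x),
    "TEXPD" = function() fit_texpd(x, tau = tau_te)
  )
  fits <- lapply(fitters, function(f) tryCatch(f(), error = function(e) e))
  gof <- lapply(fits, function(f) {
    if (inherits(f, "error")) return(list(ks = NA_real_, cvm = NA_real_, ad = NA_real_))
    tryCatch(gof_stats(x, function(q) model_cdf(f, q)),
             error = function(e) list(ks = NA_real_, cvm = NA_real_, ad = NA_real_))
  })
  tab <- data.frame(
    model = names(fits),
    loglik = vapply(fits, function(f) if (inherits(f, "error")) NA_real_ else f$loglik, 0),
    k = vapply(fits, function(f) if (inherits(f, "error")) NA_integer_ else as.integer(f$k), 0L),
    aic = vapply(fits, function(f) if (inherits(f, "error")) NA_real_ else f$aic, 0),
    bic = vapply(fits, function(f) if (inherits(f, "error")) NA_real_ else f$bic, 0),
    ks = vapply(gof, `[[`, 0, "ks"),
    cvm = vapply(gof, `[[`, 0, "cvm"),
    ad = vapply(gof, `[[`, 0, "ad"),
    row.names = NULL
  )
  ord <- order(tab$aic, tab$bic, tab$model, na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(sample_name = name, n = length(x), fits = fits,
                 gof = gof, table = tab),
            class = "wtexpd_comparison")
}

#' @export
print.wtexpd_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Model comparison for '%s' (n = %d), ranked by AIC\n",
              x$sample_name, x$n))
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  failed <- names(x$fits)[vapply(x$fits, inherits, TRUE, "error")]
  if (length(failed))
    cat("failed fits:", paste(failed, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.wtexpd_comparison <- function(x, ...) x$table
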