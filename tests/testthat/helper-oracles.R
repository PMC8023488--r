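# shared numeric oracles, independent of the analytic code paths they check

# central finite-difference gradient of f at x
fd_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    h <- eps * max(abs(x[i]), 1)
    e <- replace(numeric(length(x)), i, h)
    (f(x + e) - f(x - e)) / (2 * h)
  }, 0)
}

# central finite-difference Hessian of f at x
fd_hessian <- function(f, x, eps = 1e-4) {
  k <- length(x)
  h <- eps * pmax(abs(x), 1)
  H <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    ej <- replace(numeric(k), j, h[j])
    H[i, j] <- (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
                f(x - ei - ej)) / (4 * h[i] * h[j])
  }
  (H + t(H)) / 2
}

# random valid parameter triples (tau, lambda, beta), reproducible
random_params <- function(k, seed = 421) {
  set.seed(seed)
  data.frame(tau = runif(k, -2, 5),
             lambda = exp(runif(k, -1, 2)),
             beta = exp(runif(k, log(0.5), log(4))))
}

# brute-force Kolmogorov-Smirnov: the sup of |Fn - F| is attained at a data
# point, from the ECDF's value or its left limit; enumerate all candidates
ks_brute <- function(x, cdf_fn) {
  u <- sort(unique(x))
  right <- ecdf(x)(u)
  left <- c(0, right[-length(right)])
  Fu <- cdf_fn(u)
  max(pmax(abs(right - Fu), abs(left - Fu)))
}

# absolute-difference expectation, for values published at fixed decimals
expect_close <- function(actual, published, tol) {
  expect_lt(abs(actual - published), tol)
}

integrate_ <- function(f, lower, upper, ...) {
  stats::integrate(f, lower, upper, rel.tol = 1e-10, abs.tol = 1e-12,
                   subdivisions = 500L, ...)$value
}
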