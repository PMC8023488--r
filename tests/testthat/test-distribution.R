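test_that("density special values and support boundary", {
  expect_equal(dwtexpd(1, tau = 0, alpha = 1, theta = 1, beta = 1), exp(-1))
  expect_equal(dwtexpd(c(-1, 0, 1), tau = 2, alpha = 3, theta = 1, beta = 1.7),
               c(0, 0, 0))
  # boundary: 0 for beta > 1, continuous limit 1/lambda for beta = 1,
  # divergent (with a warning) for beta < 1
  expect_equal(dwtexpd(2, tau = 2, alpha = 3, theta = 1, beta = 1.7), 0)
  expect_equal(dwtexpd(2, tau = 2, alpha = 4, theta = 1, beta = 1), 0.25)
  expect_warning(d0 <- dwtexpd(2, tau = 2, alpha = 3, theta = 1, beta = 0.7),
                 "diverges")
  expect_identical(d0, Inf)
  expect_error(dwtexpd(1, beta = -1), "beta")
  expect_error(dwtexpd(1, alpha = -1, theta = 1), "lambda")
})

test_that("density integrates to one over the support", {
  # spec-level check at one triple to 1e-8 ...
  expect_equal(
    integrate_(function(x) dwtexpd(x, 2, 3, 1, 1.7), 2, Inf), 1,
    tolerance = 1e-8)
  # ... and as a property over 50 random valid triples
  ps <- random_params(50)
  for (i in seq_len(nrow(ps))) {
    tot <- integrate_(function(x) dwtexpd(x, ps$tau[i], ps$lambda[i], 1, ps$beta[i]),
                      ps$tau[i], Inf)
    expect_equal(tot, 1, tolerance = 1e-8)
  }
})

test_that("cdf matches quadrature of the density and has the right limits", {
  expect_equal(pwtexpd(5, tau = 5, alpha = 2, theta = 1, beta = 0.8), 0)
  expect_equal(pwtexpd(3, tau = 1, alpha = 2, theta = 1, beta = 3.1),
               1 - exp(-1))
  grid <- 1 + 2 * seq(0.05, 6, length.out = 50)
  for (q in grid) {
    expect_equal(pwtexpd(q, 1, 2, 1, 0.8),
                 integrate_(function(x) dwtexpd(x, 1, 2, 1, 0.8), 1, q),
                 tolerance = 1e-8)
  }
  expect_true(all(diff(pwtexpd(grid, 1, 2, 1, 0.8)) >= 0))
  expect_equal(pwtexpd(1e8, 1, 2, 1, 0.8), 1, tolerance = 1e-12)
})

test_that("survival complements the cdf", {
  x <- seq(0.1, 20, length.out = 40)
  expect_equal(swtexpd(x, 0, 1.5, 1, 2.2) + pwtexpd(x, 0, 1.5, 1, 2.2),
               rep(1, 40), tolerance = 1e-12)
  expect_equal(swtexpd(3, tau = 3), 1)
  expect_equal(swtexpd(4, tau = 3, alpha = 1), exp(-1))
})

test_that("quantile inverts the cdf (corrected percentile form)", {
  expect_equal(qwtexpd(0, tau = 7, alpha = 2, theta = 1, beta = 3), 7)
  expect_equal(qwtexpd(1 - exp(-1), 0, 1, 1, 2.7), 1)
  # P = 0.5, tau 2, lambda 3, beta 2 -> 2 + 3 sqrt(ln 2); cross-checked by
  # root-finding on the cdf
  q <- qwtexpd(0.5, 2, 3, 1, 2)
  expect_equal(q, 2 + 3 * sqrt(log(2)), tolerance = 1e-12)
  root <- uniroot(function(x) pwtexpd(x, 2, 3, 1, 2) - 0.5, c(2.0001, 50),
                  tol = 1e-12)$root
  expect_equal(q, root, tolerance = 1e-8)
  P <- seq(0.01, 0.99, by = 0.01)
  ps <- random_params(5, seed = 99)
  for (i in 1:5) {
    expect_equal(
      pwtexpd(qwtexpd(P, ps$tau[i], ps$lambda[i], 1, ps$beta[i]),
              ps$tau[i], ps$lambda[i], 1, ps$beta[i]),
      P, tolerance = 1e-10)
    expect_true(all(diff(qwtexpd(P, ps$tau[i], ps$lambda[i], 1, ps$beta[i])) > 0))
  }
  expect_error(qwtexpd(1, 0, 1, 1, 1), "\\[0, 1\\)")
  expect_error(qwtexpd(-0.1, 0, 1, 1, 1), "\\[0, 1\\)")
})

test_that("hazard and cumulative hazard satisfy their identities", {
  expect_equal(hwtexpd(c(1, 5, 9), tau = 0.5, alpha = 2, theta = 1, beta = 1),
               rep(0.5, 3))
  expect_equal(hwtexpd(3, 0, 1, 1, 2), 6)
  t <- 0.7
  expect_equal(hwtexpd(t, 0, 1, 1, 2.5),
               dwtexpd(t, 0, 1, 1, 2.5) / swtexpd(t, 0, 1, 1, 2.5),
               tolerance = 1e-10)
  ts <- seq(0.2, 8, length.out = 25)
  expect_equal(chwtexpd(ts, 0, 1.5, 1, 0.9), -log(swtexpd(ts, 0, 1.5, 1, 0.9)),
               tolerance = 1e-10)
  expect_equal(chwtexpd(0, 0, 1.5, 1, 0.9), 0)
  expect_equal(chwtexpd(1.5, 0, 1.5, 1, 0.9), 1)
  expect_equal(chwtexpd(2, 0, 1.5, 1, 0.9),
               integrate_(function(u) hwtexpd(u, 0, 1.5, 1, 0.9), 0, 2),
               tolerance = 1e-6)
  # monotonicity regimes of the hazard
  expect_true(all(diff(hwtexpd(ts, 0, 1, 1, 1.8)) > 0))
  expect_true(all(diff(hwtexpd(ts, 0, 1, 1, 0.6)) < 0))
  expect_error(hwtexpd(0.5, tau = 1), "t > tau")
  expect_error(chwtexpd(0.5, tau = 1), "t >= tau")
})

test_that("special cases reduce to exponential and three-parameter Weibull", {
  x <- seq(0.05, 10, length.out = 60)
  theta0 <- 2.5  # alpha = 1/theta0, theta = 1, beta = 1 is Exponential(theta0)
  expect_equal(dwtexpd(x, 0, 1 / theta0, 1, 1), dexp(x, theta0),
               tolerance = 1e-12)
  expect_equal(dwtexpd(x + 1.3, 1.3, 2.2, 1, 1.7),
               dweibull(x, 1.7, 2.2), tolerance = 1e-12)
  expect_equal(pwtexpd(x + 1.3, 1.3, 2.2, 1, 1.7),
               pweibull(x, 1.7, 2.2), tolerance = 1e-12)
})

test_that("the scale pair matters only through its ratio", {
  x <- seq(2.1, 15, length.out = 30)
  for (cc in c(2, 0.3, -1, -7.5)) {
    expect_equal(dwtexpd(x, 2, cc * 3, cc * 1, 1.4), dwtexpd(x, 2, 3, 1, 1.4))
    expect_equal(pwtexpd(x, 2, cc * 3, cc * 1, 1.4), pwtexpd(x, 2, 3, 1, 1.4))
    expect_equal(qwtexpd(0.37, 2, cc * 3, cc * 1, 1.4), qwtexpd(0.37, 2, 3, 1, 1.4))
  }
})

test_that("random generation is seed-reproducible and respects the support", {
  set.seed(11); a <- rwtexpd(5, 1, 2, 1, 1.5)
  set.seed(11); b <- rwtexpd(5, 1, 2, 1, 1.5)
  expect_identical(a, b)
  set.seed(3)
  expect_true(all(rwtexpd(1000, tau = 7, alpha = 0.5, theta = 1, beta = 0.8) > 7))
  set.seed(4)
  m <- mean(rwtexpd(1e5, 0, 1, 1, 1))
  expect_lt(abs(m - 1), 3 / sqrt(1e5))
  expect_error(rwtexpd(0), "positive integer")
})

test_that("order-statistic density is normalized and hits known cases", {
  x <- seq(0.05, 6, length.out = 40)
  expect_equal(dwtexpd_order(x, 1, 1, 0, 1, 1, 1.3), dwtexpd(x, 0, 1, 1, 1.3))
  # minimum of 5 unit exponentials is Exponential(rate 5)
  expect_equal(dwtexpd_order(0.2, 1, 5, 0, 1, 1, 1), 5 * exp(-1),
               tolerance = 1e-12)
  expect_equal(dwtexpd_order(x, 1, 5, 0, 1, 1, 1), dexp(x, 5), tolerance = 1e-12)
  # maximum of 3: 3 F^2 f, integrates to one
  expect_equal(
    integrate_(function(u) dwtexpd_order(u, 3, 3, 0, 1, 1, 1), 0, Inf), 1,
    tolerance = 1e-8)
  expect_equal(
    integrate_(function(u) dwtexpd_order(u, 2, 4, 1, 2, 1, 1.6), 1, Inf), 1,
    tolerance = 1e-8)
  expect_error(dwtexpd_order(1, 3, 2), "1 <= r <= n")
})
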