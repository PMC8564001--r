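test_that("beta mean-precision density matches a direct log-gamma oracle", {
  direct <- function(y, mu, phi) {
    a <- mu * phi; b <- (1 - mu) * phi
    (a - 1) * log(y) + (b - 1) * log1p(-y) -
      (lgamma(a) + lgamma(b) - lgamma(a + b))
  }
  grid <- expand.grid(y = c(0.01, 0.2, 0.5, 0.8, 0.99),
                      mu = c(0.05, 0.3, 0.5, 0.7, 0.95),
                      phi = c(0.5, 2, 22.7, 100))
  got <- dbeta_mp(grid$y, grid$mu, grid$phi, log = TRUE)
  expect_lt(max(abs(got - with(grid, direct(y, mu, phi)))), 1e-10)
  # Beta(mu = 0.5, phi = 2) is Uniform(0, 1)
  expect_equal(dbeta_mp(0.5, 0.5, 2, log = TRUE), 0)
  expect_equal(dbeta_mp(0.123, 0.5, 2), 1)
})

test_that("density integrates to one and variance identity holds", {
  for (mu in c(0.3, 0.5, 0.58)) {
    for (phi in c(2, 22.7)) {
      q <- stats::integrate(function(y) dbeta_mp(y, mu, phi), 0, 1,
                            rel.tol = 1e-10)
      expect_equal(q$value, 1, tolerance = 1e-6)
    }
  }
  expect_equal(beta_mp_var(0.5, 22.7), 0.25 / 23.7, tolerance = 1e-12)
  set.seed(42)
  draws <- rbeta_mp(1e6, 0.5, 22.7)
  expect_equal(var(draws), beta_mp_var(0.5, 22.7), tolerance = 0.01)
})

test_that("boundary and invalid inputs are rejected", {
  expect_error(dbeta_mp(0, 0.5, 2), "strictly inside")
  expect_error(dbeta_mp(1, 0.5, 2), "strictly inside")
  expect_error(dbeta_mp(0.5, 0.5, -1))
})

test_that("mixture log-likelihood matches the naive-summation oracle", {
  naive <- function(y, mu1, mu2, phi1, phi2, p)
    log((1 - p) * dbeta_mp(y, mu1, phi1) + p * dbeta_mp(y, mu2, phi2))
  # parameter values of the fitted structure mixture
  mu1 <- plogis(0.01); mu2 <- plogis(0.33)
  expect_equal(mixture_loglik(0.55, mu1, mu2, 23.31, 11.41, 0.19),
               naive(0.55, mu1, mu2, 23.31, 11.41, 0.19),
               tolerance = 1e-10)
  ys <- seq(0.05, 0.95, by = 0.05)
  for (p in c(0.01, 0.19, 0.5, 0.99))
    expect_equal(mixture_loglik(ys, mu1, mu2, 23.31, 11.41, p),
                 naive(ys, mu1, mu2, 23.31, 11.41, p), tolerance = 1e-10)
})

test_that("mixture degenerates correctly and is continuous in pi", {
  expect_equal(mixture_loglik(0.4, 0.5, 0.6, 20, 10, 0),
               dbeta_mp(0.4, 0.5, 20, log = TRUE))
  expect_equal(mixture_loglik(0.4, 0.5, 0.6, 20, 10, 1),
               dbeta_mp(0.4, 0.6, 10, log = TRUE))
  # identical components: any pi gives the common density
  expect_equal(mixture_loglik(0.4, 0.55, 0.55, 15, 15, 0.5),
               dbeta_mp(0.4, 0.55, 15, log = TRUE))
  # continuity near the edges
  eps_path <- vapply(c(1e-12, 1e-8, 1e-4),
                     function(e) mixture_loglik(0.4, 0.5, 0.6, 20, 10, e),
                     numeric(1))
  expect_lt(max(abs(eps_path - mixture_loglik(0.4, 0.5, 0.6, 20, 10, 0))),
            1e-3)
  expect_error(mixture_loglik(0.4, 0.5, 0.6, 20, 10, 1.2), "\\[0, 1\\]")
})
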