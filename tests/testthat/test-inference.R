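test_that("summaries convert draw-wise to the probability scale", {
  # near-point-mass at logit 0.33 -> probability-scale mean 0.58 (2 dp)
  draws <- cbind(b_intercept = rep(0.33, 100))
  s <- summarize_fit(draws, pars = "b_intercept")
  expect_equal(round(s$p_mean, 2), 0.58)
  draws0 <- cbind(b_intercept = rep(0, 100))
  expect_equal(summarize_fit(draws0, pars = "b_intercept")$p_mean, 0.5)
  # symmetric posterior centered at 0: direction probability ~0.5
  set.seed(20)
  sym <- cbind(b_intercept = rnorm(20000))
  s2 <- summarize_fit(sym, pars = "b_intercept")
  expect_equal(s2$prob_direction, 0.5, tolerance = 0.02)
  expect_true(s2$ci_low <= s2$mean && s2$mean <= s2$ci_high)
  expect_error(summarize_fit(sym, pars = "nope"), "unknown parameter")
})

test_that("probability-scale quantiles commute with the inverse logit", {
  set.seed(21)
  x <- rnorm(5000, 0.3, 0.6)
  draws <- cbind(b_intercept = x)
  s <- summarize_fit(draws, pars = "b_intercept")
  # interpolation between order statistics introduces ~1e-8 differences
  expect_equal(s$p_ci_low, plogis(quantile(x, 0.025, names = FALSE)),
               tolerance = 1e-6)
  expect_equal(s$p_ci_high, plogis(quantile(x, 0.975, names = FALSE)),
               tolerance = 1e-6)
})

test_that("diagnostics distinguish mixed from unmixed chains", {
  set.seed(22)
  good <- rnorm(2000)
  chain <- rep(1:2, each = 1000)
  expect_lt(split_rhat(good, chain), 1.01)
  expect_gt(ess_basic(good, chain), 1000)
  bad <- c(rnorm(1000, 0), rnorm(1000, 3))
  expect_gt(split_rhat(bad, chain), 1.5)
})

test_that("Gauss-Hermite quadrature integrates Gaussian moments", {
  gh <- gauss_hermite(21)
  # int x^2 exp(-x^2) dx = sqrt(pi)/2
  expect_equal(sum(gh$weights * gh$nodes^2), sqrt(pi) / 2, tolerance = 1e-10)
  expect_equal(sum(gh$weights), sqrt(pi), tolerance = 1e-10)
})

test_that("a model compared to itself has zero LOO difference", {
  set.seed(23)
  ll <- matrix(rnorm(500 * 15, -1, 0.3), 500, 15)
  loo <- psis_loo(ll)
  cmp <- loo_compare(loo, loo)
  expect_equal(cmp$elpd_diff, 0)
  expect_equal(cmp$se_diff, 0)
  expect_error(loo_compare(loo, psis_loo(ll[, 1:10])), "mismatched")
})

test_that("two identical models have a Bayes factor of one", {
  set.seed(24)
  y <- c(0.3, -0.2, 0.9)
  post_var <- 1 / (1 / 4 + 3); post_mean <- post_var * sum(y)
  lj <- function(th) sum(dnorm(y, th, 1, log = TRUE)) +
    dnorm(th, 0, 2, log = TRUE)
  d1 <- matrix(rnorm(4000, post_mean, sqrt(post_var)), ncol = 1)
  d2 <- matrix(rnorm(4000, post_mean, sqrt(post_var)), ncol = 1)
  b1 <- bridge_logml(d1, lj)
  b2 <- bridge_logml(d2, lj)
  expect_equal(b1$log_ml, b2$log_ml, tolerance = 0.02)
  expect_true(b1$converged)
  expect_lt(b1$n_bridge_iterations, 1000)
})

test_that("bridge estimates are stable under doubling the sample", {
  set.seed(25)
  y <- c(0.3, -0.2, 0.9)
  post_var <- 1 / (1 / 4 + 3); post_mean <- post_var * sum(y)
  lj <- function(th) sum(dnorm(y, th, 1, log = TRUE)) +
    dnorm(th, 0, 2, log = TRUE)
  d1 <- matrix(rnorm(2000, post_mean, sqrt(post_var)), ncol = 1)
  d2 <- matrix(rnorm(4000, post_mean, sqrt(post_var)), ncol = 1)
  b1 <- bridge_logml(d1, lj); b2 <- bridge_logml(d2, lj)
  expect_equal(b1$log_ml, b2$log_ml,
               tolerance = 3 * (b1$mc_error_estimate + b2$mc_error_estimate) +
                 0.02)
})

test_that("pairwise correlations handle the degenerate cases", {
  set.seed(26)
  x <- rnorm(30)
  w <- data.frame(a = x, b = x, c = -x, d = rnorm(30))
  pc <- pairwise_correlations(w)
  expect_equal(pc$r["a", "b"], 1)
  expect_equal(pc$r["a", "c"], -1)
  expect_lt(pc$p["a", "d"], 1.01)
  expect_error(pairwise_correlations(data.frame(a = x, b = rep(1, 30))),
               "zero variance")
  expect_error(pairwise_correlations(data.frame(a = x[1:2], b = x[1:2])),
               "3 complete pairs")
  # null sampling: mean correlation of independent columns is ~0
  set.seed(27)
  rs <- replicate(300, cor(rnorm(92), rnorm(92)))
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("parameter recovery holds for an intercept-only null world", {
  set.seed(28)
  cfg <- generative_config("graded", n_participants = 500, B0 = 0, sigma = 0,
                           phi = 22.7)
  d <- simulate_proportions(generate_participants(cfg), 1)
  fit <- fit_model(graded_spec(), d, chains = reduced_chains,
                   iter = reduced_iter, seed = 1, retries = 0)
  s <- summarize_fit(fit, pars = "b_intercept")
  expect_true(s$ci_low <= 0 && 0 <= s$ci_high)
})

test_that("condition means are constant for an intercept-only model", {
  set.seed(29)
  study <- simulate_impl_study(generative_config("graded",
                                                 n_participants = 16))
  prep <- preprocess_study(study$gaze, study$design)
  w <- prep$included
  w$y <- w$prop_target
  fit <- fit_model(chance_spec("none"), w, chains = 2, iter = 400,
                   seed = 1, retries = 0)
  cm <- condition_means(fit)
  expect_equal(nrow(cm), 4)
  expect_equal(length(unique(round(cm$mean, 10))), 1)
  fit2 <- fit_model(chance_spec("window_trial", salience = TRUE),
                    transform(w, y = prop_target),
                    chains = 2, iter = 400, seed = 1, retries = 0)
  cm2 <- condition_means(fit2)
  expect_equal(nrow(cm2), 4)
  expect_true(all(cm2$ci_low < cm2$mean & cm2$mean < cm2$ci_high))
})

test_that("fit_model validates its inputs", {
  expect_error(fit_model(graded_spec(), data.frame(y = numeric(0))), "empty")
  expect_error(fit_model(graded_spec(),
                         data.frame(participant_id = 1:3, y = c(0, 0.5, 0.7))),
               "strictly inside")
  expect_error(fit_model(discrete_spec("mu2_rt"),
                         data.frame(participant_id = 1:3,
                                    y = c(0.4, 0.5, 0.6))),
               "rt_std")
})
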