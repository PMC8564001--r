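test_that("prior intervals on the probability scale match the stated beliefs", {
  null_prior <- prior_spec("normal", 0, 0.05, scale = "logit")
  expect_equal(round(prior_interval(null_prior), 2),
               c(low = 0.48, high = 0.52))
  exp_prior <- prior_spec("exponential", 1, scale = "logit")
  expect_equal(round(prior_interval(exp_prior)[["low"]], 2), 0.51)
  # a vanishing SD collapses to a point mass at 0.5
  tight <- prior_spec("normal", 0, 1e-12, scale = "logit")
  expect_equal(unname(prior_interval(tight)), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("interval endpoints commute with the inverse logit", {
  # quantiles of monotone transforms are transforms of quantiles: compare
  # against empirical quantiles of transformed draws
  set.seed(1)
  pr <- prior_spec("normal", 0.4, 0.15, scale = "logit")
  iv <- prior_interval(pr)
  draws <- plogis(rnorm(2e5, 0.4, 0.15))
  emp <- quantile(draws, c(0.025, 0.975), names = FALSE)
  expect_equal(unname(iv), emp, tolerance = 0.002)
})

test_that("prior_spec validates arguments", {
  expect_error(prior_spec("normal", 0), "expects 2")
  expect_error(prior_spec("normal", 0, -1), "positive")
  expect_error(prior_spec("cauchy", 0, 1))
  expect_error(prior_interval(prior_spec("normal", 0, 1, scale = "natural")),
               "logit scale")
  expect_error(prior_interval(prior_spec("normal", 0, 1, scale = "logit"),
                              level = 1.2), "\\(0, 1\\)")
})
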