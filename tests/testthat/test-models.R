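test_that("sum coding follows the stated convention", {
  spec <- chance_spec("window_trial", salience = TRUE)
  obs <- data.frame(participant_id = 1, sequence_id = 1,
                    window = c(1, 1, 2, 2), trial = c(1, 2, 1, 2),
                    salience_logit = 0.1)
  dm <- build_design_matrix(obs, spec)
  # window=1, trial=2 -> (+0.5, -0.5, -0.25)
  expect_equal(unname(dm$X[2, c("window", "trial", "window:trial")]),
               c(0.5, -0.5, -0.25))
  # balanced design: sum-coded columns sum to zero
  expect_equal(colSums(dm$X[, c("window", "trial", "window:trial")]),
               c(window = 0, trial = 0, `window:trial` = 0))
  expect_error(build_design_matrix(transform(obs, window = 3), spec),
               "unknown window level")
})

test_that("items index the 16 unique trial types", {
  spec <- chance_spec("none")
  obs <- expand.grid(sequence_id = 1:8, trial = 1:2, window = 1:2)
  obs$participant_id <- seq_len(nrow(obs))
  dm <- build_design_matrix(obs, spec)
  expect_equal(length(unique(dm$item)), 16)
})

test_that("bin contrasts extend the design for the three-way model", {
  spec <- chance_spec("window_trial_bin")
  obs <- expand.grid(window = 1:2, trial = 1:2, bin = 1:4)
  obs$participant_id <- 1; obs$sequence_id <- 1
  dm <- build_design_matrix(obs, spec)
  expect_equal(ncol(dm$X), 1 + 3 + 3 + 9)
  bincols <- dm$X[, paste0("bin", 1:3)]
  expect_equal(unname(colSums(bincols)), rep(0, 3))
})

test_that("the registry carries the exact stated priors", {
  m <- model_registry()
  expect_equal(m$graded$phi_prior$distribution, "gamma")
  expect_equal(m$graded$phi_prior$pars, c(3.5, 0.5))
  expect_equal(m$graded$sigma_prior$distribution, "half_normal")
  expect_equal(m$graded$sigma_prior$pars, 1)
  expect_equal(m$bf_null$intercept_prior$pars, c(0, 0.05))
  expect_equal(m$bf_alt1$intercept_prior$pars, c(0.4, 0.15))
  expect_equal(m$bf_alt2$intercept_prior$distribution, "exponential")
  expect_equal(m$discrete$mu1_prior$pars, c(0, 0.05))
  expect_equal(m$discrete$mu2_prior$pars, c(0.4, 0.15))
  # covariate placements are exclusive
  expect_equal(m$discrete_verbs$placement, "pi_verbs")
  expect_equal(m$discrete_rt$placement, "mu2_rt")
  expect_equal(m$graded_rt$covariate, "rt")
  expect_equal(m$graded_verbs$covariate, "verbs")
  txt <- model_registry_text()
  expect_match(txt, "gamma\\(3.5, 0.5\\)")
  expect_match(txt, "\\[bf_null\\]")
  expect_match(txt, "normal\\(0, 0.05\\)")
})
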