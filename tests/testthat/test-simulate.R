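test_that("participant truths follow the generative regimes", {
  set.seed(1)
  # no heterogeneity at logit 0 -> every mu is exactly 0.5
  t0 <- generate_participants(generative_config("graded", n_participants = 50,
                                                B0 = 0, sigma = 0))
  expect_equal(t0$mu_i, rep(0.5, 50))
  # degenerate Bernoulli
  td <- generate_participants(generative_config("discrete",
                                                n_participants = 50,
                                                pi_mix = 0))
  expect_true(all(td$T_i == 0))
  tu <- generate_participants(generative_config("discrete",
                                                n_participants = 50,
                                                pi_mix = 1))
  expect_true(all(tu$T_i == 1))
  expect_error(generative_config("graded", sigma = -1), ">= 0")
  expect_error(generative_config("discrete", pi_mix = 2), "\\[0, 1\\]")
  expect_error(generative_config("smooth"))
})

test_that("large-sample mixture mean matches the closed form", {
  set.seed(2)
  cfg <- generative_config("discrete", n_participants = 10000,
                           pi_mix = 0.19, mu1_logit = 0.01,
                           mu2_logit = 0.33)
  tr <- generate_participants(cfg)
  closed <- 0.81 * plogis(0.01) + 0.19 * plogis(0.33)
  # Monte-Carlo error of the mean: component spread ~0.04 across groups
  expect_equal(mean(tr$mu_i), closed, tolerance = 0.002)
  expect_true(all(tr$mu_i > 0 & tr$mu_i < 1))
  expect_true(all(tr$n_verbs <= tr$total_vocab))
  expect_true(all(tr$rt_ms >= 200 & tr$rt_ms <= 1800))
  expect_true(all(tr$n_verbs >= 0 & tr$n_verbs <= 678))
})

test_that("covariates shift membership and group-2 mean as configured", {
  set.seed(3)
  cfg <- generative_config("discrete", n_participants = 4000, pi_mix = 0.5,
                           beta_verbs = 1.5)
  tr <- generate_participants(cfg)
  vs <- scale(tr$n_verbs)
  hi <- mean(tr$T_i[vs > 0.5]); lo <- mean(tr$T_i[vs < -0.5])
  expect_gt(hi, lo + 0.2)
})

test_that("gaze streams have the right geometry and stationary share", {
  truth <- list(participant_id = 1, mu_i = 0.5, phi_i = 22.7)
  sim <- gaze_sim_config(missing_run_prob = 0)
  set.seed(4)
  g <- generate_gaze_stream(truth, sim = sim, window_level_beta = FALSE)
  expect_equal(nrow(g), 480 * 4)  # 8 s x 60 Hz per window, 2 trials x 2
  expect_equal(sum(g$trial == 1 & g$window == 1), 480L)
  # degenerate stationary distribution
  t1 <- list(participant_id = 1, mu_i = 1 - 1e-12, phi_i = 22.7)
  g1 <- generate_gaze_stream(t1, sim = sim, window_level_beta = FALSE)
  expect_true(all(g1$aoi == "target"))
  # empirical share within 3 SE of 0.5 over many samples; the dwell chain
  # inflates the variance of the occupancy fraction by (1+rho)/(1-rho)
  set.seed(5)
  many <- do.call(rbind, replicate(50, generate_gaze_stream(
    truth, sim = sim, window_level_beta = FALSE), simplify = FALSE))
  n <- nrow(many)
  rho <- 1 - 2 / 15
  se <- sqrt(0.25 * (1 + rho) / (1 - rho) / n)
  expect_lt(abs(mean(many$aoi == "target") - 0.5), 3 * se)
})

test_that("identical seed and config give bit-identical output", {
  cfg <- generative_config("graded", n_participants = 6)
  s1 <- simulate_impl_study(cfg, seed = 99)
  s2 <- simulate_impl_study(cfg, seed = 99)
  expect_identical(s1$gaze, s2$gaze)
  expect_identical(s1$truths, s2$truths)
})

test_that("planted LWL sessions carry their ground truth", {
  set.seed(6)
  sess <- generate_lwl_session(1, planted_rts = c(650, 250, 900, 400),
                               kinds = c("clean", "clean", "target_initial",
                                         "heavy_missing"))
  plan <- attr(sess, "plan")
  expect_equal(nrow(plan), 4)
  rts <- lwl_session_rts(sess)
  expect_true(rts$eligible[1])
  expect_equal(rts$rt_ms[1], 650)
  # 250 ms is below the 300 ms lower bound
  expect_false(rts$eligible[2])
  expect_equal(rts$exclusion_reason[2], "no_shift_in_window")
  expect_equal(rts$exclusion_reason[3], "target_initial")
  expect_equal(rts$exclusion_reason[4], "low_screen_time")
  expect_error(generate_lwl_session(1, planted_rts = 5000), "strictly inside")
})

test_that("graded sigma->0 and discrete pi->0 regimes are indistinguishable", {
  set.seed(7)
  n_rej <- 0
  for (r in 1:20) {
    g <- generate_participants(generative_config("graded", n_participants = 92,
                                                 B0 = 0.01, sigma = 0,
                                                 phi = 23.31))
    d <- generate_participants(generative_config("discrete",
                                                 n_participants = 92,
                                                 pi_mix = 0,
                                                 mu1_logit = 0.01,
                                                 phi1 = 23.31))
    yg <- simulate_proportions(g, 4)$y
    yd <- simulate_proportions(d, 4)$y
    p <- suppressWarnings(stats::ks.test(yg, yd)$p.value)
    if (p < 0.01) n_rej <- n_rej + 1
  }
  expect_lte(n_rej, 2)
})

test_that("default world reproduces the observed spread of participant means", {
  set.seed(8)
  study <- simulate_impl_study(generative_config())
  prep <- preprocess_study(study$gaze, study$design)
  s <- sd(prep$participant_means$y)
  expect_gte(s, 0.06)
  expect_lte(s, 0.11)
  # and the mean sits near the observed 0.51
  expect_equal(mean(prep$participant_means$y), 0.51, tolerance = 0.02)
})

test_that("study CSVs round-trip through the documented schema", {
  cfg <- generative_config("graded", n_participants = 3)
  study <- simulate_impl_study(cfg, seed = 10)
  dir <- tempfile()
  paths <- write_study_csv(study, dir)
  gaze <- utils::read.csv(paths[["gaze"]])
  expect_setequal(names(gaze), c("participant_id", "task", "sequence_id",
                                 "trial", "window", "time_ms", "aoi"))
  expect_setequal(unique(gaze$aoi),
                  intersect(unique(gaze$aoi),
                            c("target", "distracter", "missing")))
  expect_equal(nrow(gaze), nrow(study$gaze))
  unlink(dir, recursive = TRUE)
})
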