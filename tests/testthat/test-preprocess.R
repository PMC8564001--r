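test_that("window proportions do the arithmetic and keep the accounting", {
  s <- make_window_stream(n_target = 240, n_distracter = 120, n_missing = 120)
  w <- window_proportion(s, 1, 1)
  expect_equal(w$prop_target, 240 / 360, tolerance = 1e-12)
  expect_equal(w$frac_missing, 0.25)
  expect_equal(w$n_valid, 360L)
  expect_equal(w$n_samples, 480L)
  # boundary: no target looks at all
  s0 <- make_window_stream(n_target = 0, n_distracter = 480, n_missing = 0)
  expect_equal(window_proportion(s0, 1, 1)$prop_target, 0)
  # time-origin invariance
  s2 <- s; s2$time_ms <- s2$time_ms + 12345L
  expect_equal(window_proportion(s2, 1, 1)$prop_target, w$prop_target)
})

test_that("window proportions recover the generating share", {
  set.seed(11)
  truth <- list(participant_id = 1, mu_i = 0.6, phi_i = 22.7)
  sim <- gaze_sim_config(missing_run_prob = 0)
  streams <- do.call(rbind, lapply(1:10, function(i) {
    g <- generate_gaze_stream(truth, sim = sim, window_level_beta = FALSE)
    g$participant_id <- i
    g
  }))
  ws <- window_summaries(streams)
  expect_equal(nrow(ws), 40)
  se <- sd(ws$prop_target) / sqrt(nrow(ws))
  expect_lt(abs(mean(ws$prop_target) - 0.6), 3 * se + 0.01)
})

test_that("the exclusion cascade applies both rules and is idempotent", {
  streams <- rbind(
    make_participant_windows(1, c(0.7, 0.1, 0.1, 0.1)),
    make_participant_windows(2, c(0.7, 0.7, 0.1, 0.1)),
    make_participant_windows(3, c(0, 0, 0, 0)),
    make_participant_windows(4, c(0.66, 0.1, 0.1, 0.1)))  # exactly at threshold
  ws <- window_summaries(streams)
  res <- apply_exclusions(ws)
  # participant 1: one window dropped, retained
  expect_false("1" %in% res$excluded_participants)
  expect_equal(sum(res$included$participant_id == 1), 3)
  # participant 2: two windows dropped -> excluded entirely
  expect_true("2" %in% res$excluded_participants)
  expect_equal(sum(res$included$participant_id == 2), 0)
  # clean participant: nothing excluded
  expect_equal(sum(res$included$participant_id == 3), 4)
  # threshold is inclusive: frac_missing == 0.66 drops the window
  expect_equal(sum(res$included$participant_id == 4), 3)
  expect_true(any(grepl("participant 2 EXCLUDED", res$audit)))
  # idempotence
  res2 <- apply_exclusions(res$windows)
  expect_equal(res2$included, res$included)
  expect_equal(res2$excluded_participants, res$excluded_participants)
  # a participant with fewer than four observed windows counts the absent ones
  ws5 <- window_summaries(make_participant_windows(5, c(0, 0, 0, 0)))
  res3 <- apply_exclusions(rbind(ws, ws5[1:2, ]))
  expect_true("5" %in% res3$excluded_participants)
  expect_error(apply_exclusions(rbind(ws, ws)), "duplicate")
})

test_that("every sample is accounted for", {
  set.seed(12)
  study <- simulate_impl_study(generative_config("graded", n_participants = 5))
  ws <- window_summaries(study$gaze)
  expect_true(all(ws$n_valid + round(ws$frac_missing * ws$n_samples) ==
                    ws$n_samples))
  expect_equal(sum(ws$n_samples), nrow(study$gaze))
})

test_that("the boundary transformation matches its formula", {
  expect_equal(sv_transform(0.5, 7), 0.5)
  expect_equal(sv_transform(0.5, 92), 0.5)
  expect_equal(sv_transform(0, 92), 0.5 / 92, tolerance = 1e-12)
  expect_equal(sv_transform(1, 92), 91.5 / 92, tolerance = 1e-12)
  y <- seq(0, 1, by = 0.1)
  out <- sv_transform(y, 92)
  expect_true(all(out > 0 & out < 1))
  expect_true(all(diff(out) > 0))  # monotone
  expect_error(sv_transform(0.5, 0), ">= 1")
})

test_that("binning yields four bins per window and transforms boundaries", {
  s <- make_window_stream(n_target = 480, n_distracter = 0, n_missing = 0)
  b <- bin_proportions(s)
  expect_equal(nrow(b), 4)
  expect_true(all(b$prop_target == 1))
  expect_true(all(b$prop_target_transformed < 1))
  expect_true(all(b$prop_target_transformed > 0))
  # constant stream: all bins equal before transform
  expect_equal(length(unique(b$prop_target)), 1)
  # a bin with zero valid samples is flagged
  s2 <- s
  s2$aoi[s2$time_ms < 2000] <- "missing"
  b2 <- bin_proportions(s2)
  expect_true(b2$flagged[1])
  expect_false(any(b2$flagged[-1]))
  expect_error(bin_proportions(s, bin_ms = 3000), "divisible")
})

test_that("action salience is recovered from distracter windows", {
  design <- impl_design()
  # planted world: action D attracts 0.6 of looks whenever it is the
  # distracter, others 0.5
  set.seed(13)
  rows <- list()
  for (seq_id in 1:8) for (tr in 1:2) for (pid in 1:40) {
    drow <- design[design$sequence_id == seq_id & design$trial == tr, ]
    p_dis <- if (drow$distracter_action == "D") 0.6 else 0.5
    n_dis <- rbinom(1, 480, p_dis)
    rows[[length(rows) + 1]] <- data.frame(
      participant_id = (seq_id - 1) * 40 + pid, sequence_id = seq_id,
      trial = tr, window = 1, prop_target = 1 - n_dis / 480,
      frac_missing = 0, n_valid = 480L, n_samples = 480L, excluded = FALSE)
  }
  ws <- do.call(rbind, rows)
  sal <- action_salience(ws, design)
  tab <- sal$table
  expect_equal(tab$prop_as_distracter[tab$action == "D"], 0.6,
               tolerance = 0.01)
  others <- tab$salience_logit[tab$action != "D"]
  expect_lt(max(abs(others)), 0.1)
  expect_equal(tab$salience_logit, qlogis(tab$prop_as_distracter))
  # the covariate attached to a window is the salience of its target action
  one <- sal$windows[1, ]
  expect_equal(one$salience_logit,
               tab$salience_logit[tab$action == one$target_action])
})

test_that("LWL reaction times follow the filter cascade", {
  onset <- 2500
  # clean: distracter at onset, target fixation 650-1100 ms after onset
  tr1 <- make_lwl_trial(list(list(from = onset + 650, to = onset + 1100,
                                  aoi = "target")))
  r1 <- lwl_trial_rt(tr1)
  expect_true(r1$eligible)
  expect_equal(r1$rt_ms, 650)
  # an 80 ms target look does not count as a fixation; the next >=100 ms
  # fixation at 600 ms defines the RT
  tr2 <- make_lwl_trial(list(list(from = onset + 400, to = onset + 480,
                                  aoi = "target"),
                             list(from = onset + 600, to = onset + 900,
                                  aoi = "target")))
  r2 <- lwl_trial_rt(tr2)
  expect_true(r2$eligible)
  expect_equal(r2$rt_ms, 600)
  # a shift at 250 ms is outside the 300-1800 ms window
  tr3 <- make_lwl_trial(list(list(from = onset + 250, to = onset + 700,
                                  aoi = "target")))
  expect_equal(lwl_trial_rt(tr3)$exclusion_reason, "no_shift_in_window")
  # target at onset
  tr4 <- make_lwl_trial(list(list(from = onset - 200, to = onset + 900,
                                  aoi = "target")))
  expect_equal(lwl_trial_rt(tr4)$exclusion_reason, "target_initial")
  # mostly off screen in the 3000 ms window
  tr5 <- make_lwl_trial(list(list(from = onset + 100, to = onset + 2000,
                                  aoi = "missing")))
  expect_equal(lwl_trial_rt(tr5)$exclusion_reason, "low_screen_time")
  expect_error(lwl_trial_rt(tr1, target_onset_ms = 99999), "outside")
})

test_that("participant RT averages eligible trials only", {
  recs <- data.frame(eligible = c(TRUE, TRUE, FALSE),
                     rt_ms = c(400, 600, NA))
  expect_equal(participant_rt(recs), 500)
  expect_equal(participant_rt(recs[2, ]), 600)
  expect_warning(val <- participant_rt(recs[3, ]), "no eligible")
  expect_true(is.na(val))
  # generator round trip: planted RTs recovered exactly, so the mean is too
  set.seed(14)
  planted <- c(500, 750, 1200, 333)
  sess <- generate_lwl_session(9, planted)
  rts <- lwl_session_rts(sess)
  expect_equal(rts$rt_ms, planted)
  expect_equal(participant_rt(rts), mean(planted))
})

test_that("standardization has unit moments and round-trips", {
  z <- standardize_covariate(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1, 0, 1))
  expect_error(standardize_covariate(rep(2, 5)), "zero variance")
  expect_error(standardize_covariate(c(1, NA)), "non-missing")
  set.seed(15)
  x <- rnorm(50, 100, 7); x[4] <- NA
  z <- standardize_covariate(x)
  expect_true(is.na(z[4]))
  expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(sd(z, na.rm = TRUE), 1, tolerance = 1e-12)
  back <- as.numeric(z) * attr(z, "scale") + attr(z, "center")
  expect_equal(back, x, tolerance = 1e-12)
})

test_that("preprocess_study assembles the participant-level response", {
  set.seed(16)
  study <- simulate_impl_study(generative_config("graded",
                                                 n_participants = 12))
  covs <- participant_covariates(study$truths)
  prep <- preprocess_study(study$gaze, study$design, covariates = covs)
  pm <- prep$participant_means
  expect_true(all(pm$y > 0 & pm$y < 1))
  expect_true(all(c("rt_std", "verbs_std") %in% names(pm)))
  # response is the mean over that participant's included windows
  p1 <- prep$included[prep$included$participant_id == pm$participant_id[1], ]
  expect_equal(pm$y[1], mean(p1$prop_target), tolerance = 1e-9)
})
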