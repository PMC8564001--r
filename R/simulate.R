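#' Configuration of the generative regimes
#'
#' Describes the ground-truth world the synthetic-data generator draws
#' from. Two regimes are available:
#'
#' * `"graded"`: every participant has their own mean looking proportion,
#'   `mu_i = inv_logit(B0 + t_i)` with `t_i ~ Normal(0, sigma)`; window
#'   proportions scatter around `mu_i` with beta precision `phi`.
#' * `"discrete"`: participants belong to one of two latent groups,
#'   `T_i ~ Bernoulli(pi)`, a chance-level group with mean
#'   `inv_logit(mu1_logit)` and precision `phi1`, and an above-chance
#'   group with mean `inv_logit(mu2_logit)` and precision `phi2`.
#'
#' Optional covariate effects mirror the two tested model extensions:
#' `beta_verbs` moves the membership logit with the standardized verb
#' count (discrete regime) or the mean logit (graded regime); `beta_rt`
#' moves the group-2 mean logit (discrete) or the mean logit (graded)
#' with the standardized lexical-processing RT.
#'
#' Defaults are the fitted values reported for the study data: intercept
#' 0.04 logit (mean proportion ~0.51), random-effect SD 0.08, precision
#' 22.7; mixture components at logits 0.01 and 0.33 with precisions 23.31
#' and 11.41 and membership probability 0.17; covariates with RT mean
#' 563 ms (SD 111.7) and verb count mean 54.6 (SD 30.2).
#'
#' @param regime `"graded"` or `"discrete"`.
#' @param n_participants number of participants (default 92).
#' @param B0 logit-scale grand intercept (graded regime).
#' @param sigma SD of participant deviations `t_i` (graded), `>= 0`.
#' @param phi beta precision of window proportions (graded).
#' @param pi_mix membership probability of the above-chance group.
#' @param mu1_logit,mu2_logit component means on the logit scale.
#' @param phi1,phi2 component precisions.
#' @param beta_rt effect of standardized RT (see Details).
#' @param beta_verbs effect of standardized verb count (see Details).
#' @param rt_mean,rt_sd,verbs_mean,verbs_sd,vocab_mean,vocab_sd covariate
#'   population moments.
#' @return an object of class `generative_config`.
#' @export
generative_config <- function(regime = c("graded", "discrete"),
                              n_participants = 92,
                              B0 = 0.04, sigma = 0.08, phi = 22.7,
                              pi_mix = 0.17,
                              mu1_logit = 0.01, mu2_logit = 0.33,
                              phi1 = 23.31, phi2 = 11.41,
                              beta_rt = 0, beta_verbs = 0,
                              rt_mean = 563, rt_sd = 111.7,
                              verbs_mean = 54.6, verbs_sd = 30.2,
                              vocab_mean = 350.9, vocab_sd = 151.8) {
  regime <- match.arg(regime)
  cfg <- list(regime = regime, n_participants = as.integer(n_participants),
              B0 = B0, sigma = sigma, phi = phi, pi_mix = pi_mix,
              mu1_logit = mu1_logit, mu2_logit = mu2_logit,
              phi1 = phi1, phi2 = phi2,
              beta_rt = beta_rt, beta_verbs = beta_verbs,
              rt_mean = rt_mean, rt_sd = rt_sd,
              verbs_mean = verbs_mean, verbs_sd = verbs_sd,
              vocab_mean = vocab_mean, vocab_sd = vocab_sd)
  with(cfg, {
    if (n_participants < 1) stop("n_participants must be >= 1")
    if (sigma < 0) stop("sigma must be >= 0")
    if (phi <= 0 || phi1 <= 0 || phi2 <= 0) stop("precisions must be > 0")
    if (pi_mix < 0 || pi_mix > 1) stop("pi_mix must lie in [0, 1]")
    if (!all(is.finite(unlist(cfg[-1])))) stop("parameters must be finite")
  })
  structure(cfg, class = "generative_config")
}

#' Task geometry of the simulated eye-tracking session
#'
#' Durations and sampling for the simulated IMPL and looking-while-
#' listening (LWL) tasks: 60 Hz sampling, two IMPL test trials with two
#' 8-s windows each, 24 LWL trials of 7000 ms with target-word onset at
#' 2500 ms. Fixations are generated as a two-state dwell process with
#' geometric run lengths (mean dwell 500 ms at a 50/50 share) and
#' missingness is inserted as runs (mean 400 ms).
#'
#' @param sample_rate_hz sampling rate (default 60).
#' @param impl_trials,windows_per_trial,window_ms IMPL structure.
#' @param lwl_trials,lwl_trial_ms,lwl_target_onset_ms LWL structure.
#' @param mean_dwell_ms mean fixation run length at an even share.
#' @param missing_run_prob per-sample probability of starting a missing run.
#' @param missing_mean_run_ms mean missing-run length.
#' @return an object of class `gaze_sim_config`.
#' @export
gaze_sim_config <- function(sample_rate_hz = 60, impl_trials = 2,
                            windows_per_trial = 2, window_ms = 8000,
                            lwl_trials = 24, lwl_trial_ms = 7000,
                            lwl_target_onset_ms = 2500,
                            mean_dwell_ms = 500, missing_run_prob = 0.005,
                            missing_mean_run_ms = 400) {
  cfg <- list(sample_rate_hz = sample_rate_hz, impl_trials = impl_trials,
              windows_per_trial = windows_per_trial, window_ms = window_ms,
              lwl_trials = lwl_trials, lwl_trial_ms = lwl_trial_ms,
              lwl_target_onset_ms = lwl_target_onset_ms,
              mean_dwell_ms = mean_dwell_ms,
              missing_run_prob = missing_run_prob,
              missing_mean_run_ms = missing_mean_run_ms)
  if (any(unlist(cfg[c("sample_rate_hz", "window_ms", "lwl_trial_ms",
                       "mean_dwell_ms", "missing_mean_run_ms")]) <= 0))
    stop("durations and the sampling rate must be positive")
  structure(cfg, class = "gaze_sim_config")
}

truncated_normal <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' Draw participant-level ground truth
#'
#' Realizes one record per participant: covariates (LWL reaction time in
#' ms truncated to \[200, 1800\]; verb count truncated to \[0, 678\];
#' total vocabulary at least the verb count, at most 678) and the latent
#' looking propensity. Under the graded regime `mu_i = inv_logit(B0 +
#' beta_verbs * verbs_std + beta_rt * rt_std + t_i)` with `t_i ~
#' Normal(0, sigma)`. Under the discrete regime `T_i ~ Bernoulli(pi_i)`
#' with `pi_i = inv_logit(qlogis(pi_mix) + beta_verbs * verbs_std)` when
#' `beta_verbs != 0` (else constant `pi_mix`), and `mu_i` equal to the
#' group-1 mean or to `inv_logit(mu2_logit + beta_rt * rt_std)`.
#'
#' @param config a [generative_config()].
#' @return data.frame with one row per participant: `participant_id`,
#'   `regime`, `t_i`, `T_i`, `mu_i`, `phi_i`, `rt_ms`, `n_verbs`,
#'   `total_vocab`.
#' @export
generate_participants <- function(config) {
  stopifnot(inherits(config, "generative_config"))
  n <- config$n_participants
  rt <- truncated_normal(n, config$rt_mean, config$rt_sd, 200, 1800)
  verbs <- round(truncated_normal(n, config$verbs_mean, config$verbs_sd, 0, 678))
  vocab <- round(truncated_normal(n, config$vocab_mean, config$vocab_sd, 0, 678))
  vocab <- pmax(vocab, verbs)
  rt_std <- if (n > 1 && stats::sd(rt) > 0) (rt - mean(rt)) / stats::sd(rt) else rep(0, n)
  verbs_std <- if (n > 1 && stats::sd(verbs) > 0) (verbs - mean(verbs)) / stats::sd(verbs) else rep(0, n)

  if (config$regime == "graded") {
    t_i <- stats::rnorm(n, 0, config$sigma)
    eta <- config$B0 + config$beta_verbs * verbs_std +
      config$beta_rt * rt_std + t_i
    mu <- stats::plogis(eta)
    T_i <- NA_integer_
    phi_i <- rep(config$phi, n)
  } else {
    eta_pi <- if (config$beta_verbs != 0)
      stats::qlogis(config$pi_mix) + config$beta_verbs * verbs_std
    else stats::qlogis(config$pi_mix)
    p_i <- stats::plogis(eta_pi)
    if (config$pi_mix == 0) p_i <- rep(0, n)
    if (config$pi_mix == 1) p_i <- rep(1, n)
    T_i <- stats::rbinom(n, 1, p_i)
    mu2 <- stats::plogis(config$mu2_logit + config$beta_rt * rt_std)
    mu <- ifelse(T_i == 1, mu2, stats::plogis(config$mu1_logit))
    t_i <- NA_real_
    phi_i <- ifelse(T_i == 1, config$phi2, config$phi1)
  }
  eps <- 1e-12
  mu <- pmin(pmax(mu, eps), 1 - eps)
  data.frame(participant_id = seq_len(n), regime = config$regime,
             t_i = t_i, T_i = T_i, mu_i = mu, phi_i = phi_i,
             rt_ms = rt, n_verbs = as.integer(verbs),
             total_vocab = as.integer(vocab), stringsAsFactors = FALSE)
}

#' Draw beta-distributed proportions from participant truths
#'
#' Convenience generator used by the recovery experiments: draws
#' `obs_per_participant` proportions per participant directly from the
#' beta law `Beta(mu_i, phi_i)` (mean-precision), bypassing the gaze
#' microstructure.
#'
#' @param truths output of [generate_participants()].
#' @param obs_per_participant observations per participant.
#' @return data.frame with `participant_id`, `obs`, `y`.
#' @export
simulate_proportions <- function(truths, obs_per_participant = 1) {
  n <- nrow(truths)
  k <- obs_per_participant
  y <- rbeta_mp(n * k, rep(truths$mu_i, each = k), rep(truths$phi_i, each = k))
  eps <- 1e-9
  y <- pmin(pmax(y, eps), 1 - eps)
  data.frame(participant_id = rep(truths$participant_id, each = k),
             obs = rep(seq_len(k), times = n), y = y)
}

dwell_chain <- function(n_samples, share, dwell_samples) {
  # two-state Markov chain over {target, distracter} whose stationary
  # target share is `share`; mean run length 2*dwell_samples at share 0.5
  share <- min(max(share, 1e-9), 1 - 1e-9)
  q_t <- min((1 - share) / dwell_samples, 1)  # leave target
  q_d <- min(share / dwell_samples, 1)        # leave distracter
  state <- integer(n_samples)
  s <- if (stats::runif(1) < share) 1L else 0L  # 1 = target
  u <- stats::runif(n_samples)
  for (i in seq_len(n_samples)) {
    state[i] <- s
    if (s == 1L) { if (u[i] < q_t) s <- 0L } else { if (u[i] < q_d) s <- 1L }
  }
  state
}

insert_missing_runs <- function(aoi, run_prob, mean_run_samples) {
  if (run_prob <= 0) return(aoi)
  n <- length(aoi)
  i <- 1L
  while (i <= n) {
    if (stats::runif(1) < run_prob) {
      len <- 1L + stats::rgeom(1, 1 / mean_run_samples)
      aoi[i:min(n, i + len - 1L)] <- "missing"
      i <- i + len
    } else i <- i + 1L
  }
  aoi
}

#' Simulate a 60 Hz IMPL gaze stream for one participant
#'
#' For each of the trials and 8-s windows, a per-window target share is
#' drawn from `Beta(mu_i, phi_i)` and a two-state dwell process is run at
#' the sampling rate so that looks come in contiguous fixation runs whose
#' stationary target share equals that draw; missingness is overlaid as
#' runs. With the default geometry each window contains exactly 480
#' samples (8 s at 60 Hz).
#'
#' @param truth one row of [generate_participants()] output (or a list
#'   with `participant_id`, `mu_i`, `phi_i`).
#' @param design_row row of [impl_design()] for this participant's
#'   sequence (used only for bookkeeping columns).
#' @param sim a [gaze_sim_config()].
#' @param window_level_beta draw a fresh beta share per window? If
#'   `FALSE` the dwell process runs at `mu_i` itself in every window.
#' @return long data.frame: `participant_id`, `task`, `sequence_id`,
#'   `trial`, `window`, `time_ms` (0-based within window), `aoi`.
#' @export
generate_gaze_stream <- function(truth, design_row = NULL,
                                 sim = gaze_sim_config(),
                                 window_level_beta = TRUE) {
  stopifnot(truth$mu_i > 0, truth$mu_i < 1)
  period_ms <- 1000 / sim$sample_rate_hz
  n_per_window <- round(sim$window_ms / period_ms)
  dwell_samples <- sim$mean_dwell_ms / period_ms / 2
  seq_id <- if (is.null(design_row)) NA_integer_ else design_row$sequence_id[1]
  out <- vector("list", sim$impl_trials * sim$windows_per_trial)
  k <- 0L
  for (tr in seq_len(sim$impl_trials)) {
    for (w in seq_len(sim$windows_per_trial)) {
      share <- if (window_level_beta)
        rbeta_mp(1, truth$mu_i, truth$phi_i) else truth$mu_i
      st <- dwell_chain(n_per_window, share, dwell_samples)
      aoi <- ifelse(st == 1L, "target", "distracter")
      aoi <- insert_missing_runs(aoi, sim$missing_run_prob,
                                 sim$missing_mean_run_ms / period_ms)
      k <- k + 1L
      out[[k]] <- data.frame(
        participant_id = truth$participant_id, task = "impl",
        sequence_id = seq_id, trial = tr, window = w,
        time_ms = as.integer(round((seq_len(n_per_window) - 1) * period_ms)),
        aoi = aoi, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Simulate a looking-while-listening session with planted reaction times
#'
#' Builds LWL trials with known ground truth so that downstream RT
#' extraction can be verified exactly. For a `"clean"` trial the gaze sits
#' on the distracter from before target-word onset until `planted_rt` ms
#' after onset, at which point a target fixation of at least 100 ms
#' begins. `"target_initial"` trials start on the target at onset and
#' `"heavy_missing"` trials are >50% missing in the 3000-ms post-onset
#' window; both should be rejected by the extraction filters.
#'
#' @param participant_id id for the bookkeeping column.
#' @param planted_rts vector of RTs in ms (one per trial), each within
#'   `(0, lwl_trial_ms - lwl_target_onset_ms)`.
#' @param kinds character vector, per trial: `"clean"`,
#'   `"target_initial"` or `"heavy_missing"`.
#' @param sim a [gaze_sim_config()].
#' @param fixation_ms length of the planted target fixation (>= 100).
#' @return long data.frame with `participant_id`, `task = "lwl"`, `trial`,
#'   `time_ms` (0-based within trial), `aoi`; the plan is attached as
#'   attribute `"plan"`.
#' @export
generate_lwl_session <- function(participant_id, planted_rts,
                                 kinds = rep("clean", length(planted_rts)),
                                 sim = gaze_sim_config(), fixation_ms = 600) {
  stopifnot(length(kinds) == length(planted_rts), fixation_ms >= 100)
  max_rt <- sim$lwl_trial_ms - sim$lwl_target_onset_ms
  if (any(planted_rts <= 0 | planted_rts >= max_rt))
    stop("planted RTs must lie strictly inside (0, trial length - onset)")
  period_ms <- 1000 / sim$sample_rate_hz
  n_trial <- round(sim$lwl_trial_ms / period_ms)
  onset_idx <- round(sim$lwl_target_onset_ms / period_ms)  # 0-based sample
  out <- vector("list", length(planted_rts))
  for (tr in seq_along(planted_rts)) {
    t_ms <- (seq_len(n_trial) - 1) * period_ms
    aoi <- rep("distracter", n_trial)
    # pre-onset: wandering looks, but pinned to the distracter at onset
    pre <- t_ms < sim$lwl_target_onset_ms - 500
    aoi[pre] <- sample(c("target", "distracter", "missing"), sum(pre),
                       replace = TRUE, prob = c(0.4, 0.4, 0.2))
    kind <- kinds[tr]
    rt <- planted_rts[tr]
    if (kind == "target_initial") {
      aoi[t_ms >= sim$lwl_target_onset_ms - 500] <- "target"
    } else {
      fix_start <- sim$lwl_target_onset_ms + rt
      in_fix <- t_ms >= fix_start & t_ms < fix_start + fixation_ms
      aoi[in_fix] <- "target"
      after <- t_ms >= fix_start + fixation_ms
      if (any(after))
        aoi[after] <- sample(c("target", "distracter"), sum(after),
                             replace = TRUE)
      if (kind == "heavy_missing") {
        post <- t_ms >= sim$lwl_target_onset_ms &
          t_ms < sim$lwl_target_onset_ms + 3000
        idx <- which(post)
        aoi[sample(idx, ceiling(0.6 * length(idx)))] <- "missing"
      }
    }
    out[[tr]] <- data.frame(participant_id = participant_id, task = "lwl",
                            trial = tr, time_ms = as.integer(round(t_ms)),
                            aoi = aoi, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "plan") <- data.frame(trial = seq_along(planted_rts),
                                  planted_rt = planted_rts, kind = kinds,
                                  stringsAsFactors = FALSE)
  res
}

#' Simulate a full IMPL study
#'
#' Draws participant truths, assigns counterbalancing sequences
#' cyclically, and generates a 60 Hz gaze stream per participant.
#'
#' @param config a [generative_config()].
#' @param sim a [gaze_sim_config()].
#' @param seed optional integer seed (set with [set.seed()] if given).
#' @return list with elements `truths` (data.frame), `gaze` (long
#'   data.frame), `design` ([impl_design()]), `config`, `sim`.
#' @export
simulate_impl_study <- function(config = generative_config(),
                                sim = gaze_sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truths <- generate_participants(config)
  design <- impl_design()
  truths$sequence_id <- ((truths$participant_id - 1L) %% 8L) + 1L
  gaze <- do.call(rbind, lapply(seq_len(nrow(truths)), function(i) {
    drow <- design[design$sequence_id == truths$sequence_id[i], ][1, ]
    generate_gaze_stream(truths[i, ], drow, sim)
  }))
  list(truths = truths, gaze = gaze, design = design,
       config = config, sim = sim)
}

#' Write study artifacts as CSV
#'
#' @param study output of [simulate_impl_study()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_study_csv <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(gaze = file.path(dir, "gaze.csv"),
             truths = file.path(dir, "truths.csv"),
             design = file.path(dir, "design.csv"))
  utils::write.csv(study$gaze, paths["gaze"], row.names = FALSE)
  utils::write.csv(study$truths, paths["truths"], row.names = FALSE)
  utils::write.csv(study$design, paths["design"], row.names = FALSE)
  invisible(paths)
}
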