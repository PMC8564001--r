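#' Per-window proportion of looks to the target
#'
#' Summarizes a gaze stream into one record per (participant, trial,
#' window): the proportion of looks to the target among valid samples,
#' `prop_target = target / (target + distracter)` (missing and off-video
#' samples are excluded from the denominator, the standard
#' preferential-looking convention), the fraction of samples labelled
#' missing, and the number of valid samples.
#'
#' @param stream long gaze data.frame with columns `participant_id`,
#'   `trial`, `window`, `aoi` (values `target`/`distracter`/`missing`).
#' @param trial,window optional filters selecting a single window.
#' @return data.frame with `participant_id`, `trial`, `window`,
#'   `prop_target`, `frac_missing`, `n_valid`, `n_samples`, `excluded`
#'   (always `FALSE` here; set by [apply_exclusions()]).
#' @export
window_summaries <- function(stream, trial = NULL, window = NULL) {
  need <- c("participant_id", "trial", "window", "aoi")
  if (!all(need %in% names(stream))) stop("stream lacks required columns")
  if (!is.null(trial)) stream <- stream[stream$trial == trial, ]
  if (!is.null(window)) stream <- stream[stream$window == window, ]
  if (nrow(stream) == 0)
    return(data.frame(participant_id = integer(), trial = integer(),
                      window = integer(), prop_target = numeric(),
                      frac_missing = numeric(), n_valid = integer(),
                      n_samples = integer(), excluded = logical()))
  key <- interaction(stream$participant_id, stream$trial, stream$window,
                     drop = TRUE)
  agg <- function(x) as.numeric(tapply(x, key, sum))  # in levels(key) order
  tgt <- agg(stream$aoi == "target")
  dis <- agg(stream$aoi == "distracter")
  mis <- agg(stream$aoi == "missing")
  tot <- tgt + dis + mis
  lev <- match(levels(key), as.character(key))  # first row of each cell
  out <- data.frame(
    participant_id = stream$participant_id[lev],
    trial = stream$trial[lev], window = stream$window[lev],
    prop_target = ifelse(tgt + dis > 0, tgt / (tgt + dis), NA),
    frac_missing = mis / tot,
    n_valid = as.integer(tgt + dis), n_samples = as.integer(tot),
    excluded = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$participant_id, out$trial, out$window), ]
  rownames(out) <- NULL
  out
}

#' @rdname window_summaries
#' @export
window_proportion <- function(stream, trial, window) {
  out <- window_summaries(stream, trial = trial, window = window)
  if (nrow(out) == 0) {
    out <- data.frame(participant_id = stream$participant_id[1],
                      trial = trial, window = window, prop_target = NA_real_,
                      frac_missing = 1, n_valid = 0L, n_samples = 0L,
                      excluded = TRUE)
  }
  out
}

#' Exclusion cascade for IMPL windows and participants
#'
#' Windows with at least `missing_threshold` (default 66%) missing data
#' are excluded, and participants missing two or more of their expected
#' four windows (excluded or absent) are excluded entirely. The cascade
#' is idempotent and every decision is recorded in a line-oriented audit
#' log.
#'
#' @param windows data.frame from [window_summaries()].
#' @param missing_threshold window dropped when `frac_missing >=` this.
#' @param expected_windows windows expected per participant (default 4).
#' @param max_missing_windows participant dropped when this many or more
#'   windows are excluded/absent (default 2).
#' @return list with `included` (window rows that survive), `windows`
#'   (all rows with the `excluded` flag set), `excluded_participants`
#'   (ids), and `audit` (character vector, one decision per line).
#' @export
apply_exclusions <- function(windows, missing_threshold = 0.66,
                             expected_windows = 4, max_missing_windows = 2) {
  key <- paste(windows$participant_id, windows$trial, windows$window)
  if (anyDuplicated(key)) stop("duplicate (participant, trial, window) keys")
  audit <- character()
  windows$excluded <- windows$frac_missing >= missing_threshold |
    windows$n_valid == 0
  for (i in which(windows$excluded))
    audit <- c(audit, sprintf(
      "window participant=%s trial=%d window=%d EXCLUDED frac_missing=%.3f",
      windows$participant_id[i], windows$trial[i], windows$window[i],
      windows$frac_missing[i]))
  n_bad <- tapply(windows$excluded, windows$participant_id, sum)
  n_seen <- tapply(rep(1, nrow(windows)), windows$participant_id, sum)
  n_absent <- pmax(expected_windows - n_seen, 0)
  n_missing_windows <- n_bad + n_absent
  drop_ids <- names(n_missing_windows)[n_missing_windows >= max_missing_windows]
  for (id in drop_ids)
    audit <- c(audit, sprintf(
      "participant %s EXCLUDED (%d of %d windows missing or excluded)",
      id, n_missing_windows[[id]], expected_windows))
  included <- windows[!windows$excluded &
                        !(as.character(windows$participant_id) %in% drop_ids), ]
  rownames(included) <- NULL
  list(included = included, windows = windows,
       excluded_participants = drop_ids, audit = audit)
}

#' Smithson-Verkuilen transformation of proportions
#'
#' Shrinks proportions away from the boundaries so that a beta likelihood
#' (defined on the open interval) applies: `(y * (n - 1) + 0.5) / n`,
#' where `n` is the number of proportions being transformed in the
#' dataset. The midpoint 0.5 is a fixed point; 0 and 1 map strictly
#' inside (0, 1).
#'
#' @param y proportions in \[0, 1\].
#' @param n number of observations in the dataset being transformed.
#' @return transformed proportions, strictly inside (0, 1).
#' @examples
#' sv_transform(c(0, 0.5, 1), n = 92)
#' @export
sv_transform <- function(y, n) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(y < 0 | y > 1, na.rm = TRUE)) stop("y must lie in [0, 1]")
  (y * (n - 1) + 0.5) / n
}

#' Per-bin proportions within IMPL windows
#'
#' Disaggregates each 8-s window into 2000-ms bins, computes the
#' proportion of looks to the target per bin, and applies
#' [sv_transform()] with `n` equal to the number of non-empty bin
#' proportions in the dataset (removing exact 0s and 1s). Bins with no
#' valid samples are flagged and excluded from modelling.
#'
#' @param stream long gaze data.frame (IMPL schema).
#' @param bin_ms bin width in ms; the window length must be divisible by it.
#' @param window_ms window length in ms (default 8000).
#' @return data.frame with `participant_id`, `trial`, `window`, `bin`,
#'   `prop_target`, `prop_target_transformed`, `frac_missing`, `n_valid`,
#'   `flagged`.
#' @export
bin_proportions <- function(stream, bin_ms = 2000, window_ms = 8000) {
  if (window_ms %% bin_ms != 0) stop("window length not divisible by bin_ms")
  stream$bin <- floor(stream$time_ms / bin_ms) + 1L
  key <- interaction(stream$participant_id, stream$trial, stream$window,
                     stream$bin, drop = TRUE)
  agg <- function(x) as.numeric(tapply(x, key, sum))
  tgt <- agg(stream$aoi == "target")
  dis <- agg(stream$aoi == "distracter")
  mis <- agg(stream$aoi == "missing")
  lev <- match(levels(key), as.character(key))
  out <- data.frame(
    participant_id = stream$participant_id[lev],
    trial = stream$trial[lev], window = stream$window[lev],
    bin = stream$bin[lev],
    prop_target = ifelse(tgt + dis > 0, tgt / (tgt + dis), NA),
    frac_missing = mis / (tgt + dis + mis),
    n_valid = as.integer(tgt + dis), stringsAsFactors = FALSE)
  out <- out[order(out$participant_id, out$trial, out$window, out$bin), ]
  rownames(out) <- NULL
  out$flagged <- out$n_valid == 0
  n_tr <- sum(!out$flagged)
  out$prop_target_transformed <- NA_real_
  out$prop_target_transformed[!out$flagged] <-
    sv_transform(out$prop_target[!out$flagged], n_tr)
  out
}

#' Action salience from distracter windows
#'
#' Each of the four novel actions attracts looks regardless of the
#' sentence; this baseline attractiveness is estimated as the pooled
#' proportion of looks an action draws in windows where it is the
#' distracter (weighted by valid samples), then logit-transformed. The
#' salience of the *target* action is attached to each window row as a
#' covariate, so that a model intercept reads as the increase in looks to
#' an action when it is the target relative to when it is the distracter.
#'
#' @param windows data.frame from [window_summaries()] with a
#'   `sequence_id` column or joinable via `participant_id` ->
#'   `sequence_id` mapping in `design`.
#' @param design [impl_design()]-shaped data.frame.
#' @param sequence_map optional data.frame `participant_id`, `sequence_id`
#'   if `windows` lacks `sequence_id`.
#' @return list with `table` (per-action `prop_as_distracter`,
#'   `salience_logit`) and `windows` (input rows with `target_action`,
#'   `distracter_action`, `salience_logit` of the target action attached).
#' @export
action_salience <- function(windows, design, sequence_map = NULL) {
  if (!"sequence_id" %in% names(windows)) {
    if (is.null(sequence_map)) stop("windows lacks sequence_id")
    windows <- merge(windows, sequence_map, by = "participant_id")
  }
  w <- merge(windows, design[, c("sequence_id", "trial", "target_action",
                                 "distracter_action")],
             by = c("sequence_id", "trial"))
  acts <- sort(unique(c(design$target_action, design$distracter_action)))
  tab <- do.call(rbind, lapply(acts, function(a) {
    rows <- w[w$distracter_action == a & !is.na(w$prop_target) &
                w$n_valid > 0, ]
    if (nrow(rows) == 0) stop(sprintf("action %s never occurs as distracter", a))
    p <- sum((1 - rows$prop_target) * rows$n_valid) / sum(rows$n_valid)
    if (p <= 0 || p >= 1) p <- sv_transform(p, sum(rows$n_valid))
    data.frame(action = a, prop_as_distracter = p,
               salience_logit = stats::qlogis(p), stringsAsFactors = FALSE)
  }))
  w$salience_logit <- tab$salience_logit[match(w$target_action, tab$action)]
  ord <- order(w$participant_id, w$trial, w$window)
  list(table = tab, windows = w[ord, ])
}

#' Reaction-time extraction for one looking-while-listening trial
#'
#' Implements the standard LWL filter cascade. A trial is ineligible if
#' the child was looking at the screen (either image) for less than 50%
#' of the 3000-ms window after target-word onset (`low_screen_time`), if
#' gaze was not on the distracter image at onset (`target_initial`), or
#' if the first target fixation of at least 100 ms does not begin within
#' 300-1800 ms after onset (`no_shift_in_window`). Otherwise the RT is
#' the onset-relative start time of that fixation.
#'
#' @param stream one trial of LWL gaze data (`time_ms`, `aoi`).
#' @param target_onset_ms target-word onset, ms from trial start.
#' @param screen_window_ms length of the screen-time window (3000).
#' @param rt_min_ms,rt_max_ms eligibility window for the shift (300, 1800).
#' @param min_fixation_ms minimum target fixation length (100).
#' @return one-row data.frame: `trial` (if present in input), `eligible`,
#'   `rt_ms`, `exclusion_reason` (`none`, `low_screen_time`,
#'   `target_initial`, `no_shift_in_window`).
#' @export
lwl_trial_rt <- function(stream, target_onset_ms = 2500,
                         screen_window_ms = 3000, rt_min_ms = 300,
                         rt_max_ms = 1800, min_fixation_ms = 100) {
  if (target_onset_ms < min(stream$time_ms) ||
      target_onset_ms > max(stream$time_ms))
    stop("target onset lies outside the stream")
  stream <- stream[order(stream$time_ms), ]
  trial <- if ("trial" %in% names(stream)) stream$trial[1] else NA_integer_
  res <- function(eligible, rt, reason)
    data.frame(trial = trial, eligible = eligible, rt_ms = rt,
               exclusion_reason = reason, stringsAsFactors = FALSE)

  post <- stream[stream$time_ms >= target_onset_ms &
                   stream$time_ms < target_onset_ms + screen_window_ms, ]
  on_screen <- mean(post$aoi %in% c("target", "distracter"))
  if (on_screen < 0.5) return(res(FALSE, NA_real_, "low_screen_time"))

  at_onset <- stream$aoi[max(which(stream$time_ms <= target_onset_ms))]
  if (at_onset != "distracter") return(res(FALSE, NA_real_, "target_initial"))

  after <- stream[stream$time_ms >= target_onset_ms, ]
  r <- rle(after$aoi == "target")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    fix_start <- after$time_ms[starts[j]]
    fix_end <- if (ends[j] < nrow(after)) after$time_ms[ends[j] + 1L] else
      after$time_ms[ends[j]] + diff(after$time_ms[1:2])
    if (fix_end - fix_start >= min_fixation_ms) {
      rt <- fix_start - target_onset_ms
      if (rt >= rt_min_ms && rt <= rt_max_ms) return(res(TRUE, rt, "none"))
      return(res(FALSE, NA_real_, "no_shift_in_window"))
    }
  }
  res(FALSE, NA_real_, "no_shift_in_window")
}

#' Extract RTs for a whole LWL session
#'
#' @param session long LWL gaze data.frame (multiple trials).
#' @param ... passed to [lwl_trial_rt()].
#' @return data.frame of per-trial records, plus `participant_id`.
#' @export
lwl_session_rts <- function(session, ...) {
  out <- do.call(rbind, lapply(split(session, session$trial), lwl_trial_rt, ...))
  out$participant_id <- session$participant_id[1]
  rownames(out) <- NULL
  out[, c("participant_id", "trial", "eligible", "rt_ms", "exclusion_reason")]
}

#' Mean reaction time per participant
#'
#' @param records data.frame of [lwl_trial_rt()] records.
#' @return mean of the eligible RTs in ms, or `NA` (with a warning) when
#'   no trial is eligible.
#' @export
participant_rt <- function(records) {
  ok <- records$eligible & !is.na(records$rt_ms)
  if (!any(ok)) {
    warning("no eligible LWL trials; RT covariate marked missing")
    return(NA_real_)
  }
  mean(records$rt_ms[ok])
}

#' Standardize a covariate
#'
#' Centers and scales to sample mean 0, SD 1 (denominator `n - 1`);
#' missing entries propagate and are excluded from the moments.
#'
#' @param values numeric vector with at least 2 non-missing values.
#' @return standardized vector with attributes `center` and `scale`.
#' @export
standardize_covariate <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("need at least 2 non-missing values")
  s <- stats::sd(values[ok])
  if (s == 0) stop("zero variance; cannot standardize")
  m <- mean(values[ok])
  structure((values - m) / s, center = m, scale = s)
}

#' Participant covariate table
#'
#' Combines per-participant mean LWL RT, verb counts and total vocabulary
#' and attaches standardized versions (over the included participants).
#'
#' @param truths data.frame with `participant_id`, `rt_ms` (or an
#'   `rt_mean_ms` column), `n_verbs`, `total_vocab`.
#' @return data.frame with raw and `_std` columns.
#' @export
participant_covariates <- function(truths) {
  rt <- if ("rt_mean_ms" %in% names(truths)) truths$rt_mean_ms else truths$rt_ms
  data.frame(participant_id = truths$participant_id,
             rt_mean_ms = rt, n_verbs = truths$n_verbs,
             total_vocab = truths$total_vocab,
             rt_std = as.numeric(standardize_covariate(rt)),
             verbs_std = as.numeric(standardize_covariate(truths$n_verbs)),
             stringsAsFactors = FALSE)
}

#' Preprocess a simulated or mapped study end to end
#'
#' Runs [window_summaries()], [apply_exclusions()], [action_salience()],
#' [bin_proportions()] and builds the participant-level response (mean
#' proportion across surviving windows, the quantity modelled by the
#' graded/discrete comparison). Whole-window proportions are kept raw
#' unless an exact 0/1 occurs, in which case [sv_transform()] is applied
#' and the decision logged.
#'
#' @param gaze long IMPL gaze data.frame.
#' @param design [impl_design()]-shaped data.frame.
#' @param sequence_map data.frame `participant_id`, `sequence_id`.
#' @param covariates optional covariate data.frame (see
#'   [participant_covariates()]).
#' @param missing_threshold,max_missing_windows see [apply_exclusions()].
#' @return list with `windows`, `included`, `excluded_participants`,
#'   `salience`, `bins`, `participant_means` (one row per surviving
#'   participant: `participant_id`, `y`, plus covariates when given) and
#'   `audit`.
#' @export
preprocess_study <- function(gaze, design, sequence_map = NULL,
                             covariates = NULL, missing_threshold = 0.66,
                             max_missing_windows = 2) {
  ws <- window_summaries(gaze)
  if (is.null(sequence_map) && "sequence_id" %in% names(gaze))
    sequence_map <- unique(gaze[, c("participant_id", "sequence_id")])
  excl <- apply_exclusions(ws, missing_threshold = missing_threshold,
                           max_missing_windows = max_missing_windows)
  audit <- excl$audit
  sal <- action_salience(excl$included, design, sequence_map = sequence_map)
  inc <- sal$windows
  n_prop <- nrow(inc)
  boundary <- which(inc$prop_target %in% c(0, 1))
  if (length(boundary)) {
    inc$prop_target[boundary] <- sv_transform(inc$prop_target[boundary], n_prop)
    audit <- c(audit, sprintf(
      "window participant=%s trial=%d window=%d boundary proportion sv-transformed",
      inc$participant_id[boundary], inc$trial[boundary], inc$window[boundary]))
  }
  bins <- bin_proportions(gaze)
  pm <- tapply(inc$prop_target, inc$participant_id, mean)
  participant_means <- data.frame(participant_id = as.integer(names(pm)),
                                  y = as.numeric(pm), stringsAsFactors = FALSE)
  eps <- 1e-9
  participant_means$y <- pmin(pmax(participant_means$y, eps), 1 - eps)
  if (!is.null(covariates))
    participant_means <- merge(participant_means, covariates,
                               by = "participant_id", all.x = TRUE)
  list(windows = excl$windows, included = inc,
       excluded_participants = excl$excluded_participants,
       salience = sal$table, bins = bins,
       participant_means = participant_means, audit = audit)
}
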