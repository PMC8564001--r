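# Shared fixture builders: everything is constructed in code.

# A gaze window with exact counts of target/distracter/missing samples.
make_window_stream <- function(participant_id = 1, trial = 1, window = 1,
                               n_target = 240, n_distracter = 120,
                               n_missing = 120, sequence_id = 1) {
  aoi <- c(rep("target", n_target), rep("distracter", n_distracter),
           rep("missing", n_missing))
  n <- length(aoi)
  data.frame(participant_id = participant_id, task = "impl",
             sequence_id = sequence_id, trial = trial, window = window,
             time_ms = as.integer(round((seq_len(n) - 1) * 1000 / 60)),
             aoi = aoi, stringsAsFactors = FALSE)
}

# Four windows for one participant with chosen missingness fractions.
make_participant_windows <- function(participant_id, frac_missing,
                                     prop_target = 0.5, n = 480) {
  stopifnot(length(frac_missing) == 4)
  cells <- expand.grid(trial = 1:2, window = 1:2)
  do.call(rbind, lapply(seq_len(4), function(i) {
    n_mis <- round(n * frac_missing[i])
    n_val <- n - n_mis
    n_tgt <- round(n_val * prop_target)
    make_window_stream(participant_id, cells$trial[i], cells$window[i],
                       n_target = n_tgt, n_distracter = n_val - n_tgt,
                       n_missing = n_mis)
  }))
}

# An LWL trial written sample by sample from (time, aoi) run segments.
make_lwl_trial <- function(segments, participant_id = 1, trial = 1,
                           trial_ms = 7000, hz = 60) {
  n <- round(trial_ms * hz / 1000)
  t_ms <- (seq_len(n) - 1) * 1000 / 60
  aoi <- rep("distracter", n)
  for (seg in segments)
    aoi[t_ms >= seg$from & t_ms < seg$to] <- seg$aoi
  data.frame(participant_id = participant_id, task = "lwl", trial = trial,
             time_ms = as.integer(round(t_ms)), aoi = aoi,
             stringsAsFactors = FALSE)
}

reduced_chains <- 2
reduced_iter <- 800
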