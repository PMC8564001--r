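#' Pairwise Pearson correlations with p-values
#'
#' Correlations between per-participant proportion columns (e.g. trial 1
#' vs trial 2, window 1 vs window 2), computed on pairwise-complete
#' observations with two-sided t-based p-values.
#'
#' @param wide data.frame or matrix of numeric columns (rows =
#'   participants).
#' @return list with matrices `r`, `p`, `n` (complete pairs).
#' @export
pairwise_correlations <- function(wide) {
  wide <- as.data.frame(wide)
  k <- ncol(wide)
  r <- p <- nm <- matrix(NA_real_, k, k,
                         dimnames = list(names(wide), names(wide)))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) {
    nm[i, i] <- sum(!is.na(wide[[i]]))
    for (j in seq_len(k)) {
      if (j <= i) next
      ok <- stats::complete.cases(wide[[i]], wide[[j]])
      if (sum(ok) < 3) stop("need at least 3 complete pairs")
      if (stats::sd(wide[[i]][ok]) == 0 || stats::sd(wide[[j]][ok]) == 0)
        stop("zero variance column")
      ct <- stats::cor.test(wide[[i]][ok], wide[[j]][ok])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
      nm[i, j] <- nm[j, i] <- sum(ok)
    }
  }
  list(r = r, p = p, n = nm)
}

#' Wide per-participant proportion table
#'
#' Reshapes included window summaries into one row per participant with
#' one column per (trial, window) cell, plus per-trial and per-window
#' averages, for the correlation analyses.
#'
#' @param included data.frame of included windows (from
#'   [apply_exclusions()] or [preprocess_study()]).
#' @return data.frame with columns `t<trial>_w<window>`, `trial1`,
#'   `trial2`, `window1`, `window2`.
#' @export
proportions_wide <- function(included) {
  ids <- sort(unique(included$participant_id))
  out <- data.frame(participant_id = ids)
  for (tr in 1:2) for (w in 1:2) {
    rows <- included[included$trial == tr & included$window == w, ]
    out[[sprintf("t%d_w%d", tr, w)]] <-
      rows$prop_target[match(ids, rows$participant_id)]
  }
  out$trial1 <- rowMeans(out[, c("t1_w1", "t1_w2")], na.rm = TRUE)
  out$trial2 <- rowMeans(out[, c("t2_w1", "t2_w2")], na.rm = TRUE)
  out$window1 <- rowMeans(out[, c("t1_w1", "t2_w1")], na.rm = TRUE)
  out$window2 <- rowMeans(out[, c("t1_w2", "t2_w2")], na.rm = TRUE)
  out
}
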