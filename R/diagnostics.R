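#' MCMC convergence diagnostics
#'
#' Split-R-hat (each chain halved, between/within variance ratio) and a
#' crude effective sample size from the pooled autocorrelation function
#' (Geyer initial positive sequence). A fit is flagged as non-converged
#' when any parameter's split-R-hat exceeds 1.01.
#'
#' @param fit a `lookmix_fit`.
#' @return list with `rhat` (named vector), `ess` (named vector),
#'   `max_rhat`, `converged`.
#' @export
fit_diagnostics <- function(fit) {
  draws <- fit$draws
  chain <- fit$chain
  rhat <- apply(draws, 2, split_rhat, chain = chain)
  ess <- apply(draws, 2, ess_basic, chain = chain)
  max_rhat <- max(rhat, na.rm = TRUE)
  list(rhat = rhat, ess = ess, max_rhat = max_rhat,
       converged = is.finite(max_rhat) && max_rhat <= 1.01)
}

#' @rdname fit_diagnostics
#' @param x draws of one parameter (all chains stacked).
#' @param chain integer chain id per draw.
#' @export
split_rhat <- function(x, chain) {
  halves <- lapply(split(x, chain), function(v) {
    h <- length(v) %/% 2
    list(v[seq_len(h)], v[h + seq_len(h)])
  })
  chains <- unlist(halves, recursive = FALSE)
  m <- length(chains); n <- length(chains[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @rdname fit_diagnostics
#' @export
ess_basic <- function(x, chain) {
  chains <- split(x, chain)
  n <- min(lengths(chains)); m <- length(chains)
  if (n < 4) return(NA_real_)
  if (stats::sd(x) == 0) return(m * n)
  max_lag <- min(n - 2, 500)
  acfs <- vapply(chains, function(v)
    as.numeric(stats::acf(v[seq_len(n)], lag.max = max_lag,
                          plot = FALSE, demean = TRUE)$acf), numeric(max_lag + 1))
  rho <- rowMeans(acfs)
  # Geyer: sum consecutive pairs while positive
  s <- 0; k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  tau <- max(2 * s - 1, 1e-8)
  min(m * n / tau, m * n)
}
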