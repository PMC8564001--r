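#' Fit a model by MCMC
#'
#' Fits any `lookmix_spec` by slice-within-Gibbs sampling (univariate
#' slice updates for every coordinate; random intercepts condition only
#' on their own group's observations). Defaults are 4 chains of 2000
#' iterations with the first half discarded as warmup. Convergence is
#' checked with split-R-hat; if any parameter exceeds 1.01 the fit is
#' retried once with doubled iterations and, failing that, flagged
#' loudly.
#'
#' @param spec a [graded_spec()], [discrete_spec()] or [chance_spec()].
#' @param data a data.frame; see the spec constructors for the required
#'   columns (`y` plus `participant_id`, and for chance models
#'   `sequence_id`, `trial`, `window`, optionally `bin`,
#'   `salience_logit`; for covariate models `rt_std` / `verbs_std`).
#' @param chains,iter,warmup MCMC settings.
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @param retries refits with doubled iterations on non-convergence.
#' @param ... unused.
#' @return an object of class `lookmix_fit`: draws matrix (all chains
#'   stacked, named columns), chain ids, the spec, the model data, and
#'   `diagnostics` (split-R-hat, effective sample size, `converged`).
#' @export
fit_model <- function(spec, data, chains = 4, iter = 2000,
                      warmup = floor(iter / 2), seed = 1, retries = 1, ...) {
  UseMethod("fit_model")
}

check_y <- function(y) {
  if (length(y) == 0) stop("data is empty")
  if (any(!is.finite(y)) || any(y <= 0 | y >= 1))
    stop("all responses must lie strictly inside (0, 1)")
}

prior_row <- function(prior) {
  switch(prior$distribution,
         normal = c(0, prior$pars, 0),
         student_t = c(1, prior$pars),
         exponential = c(2, prior$pars, 0, 0),
         stop("unsupported coefficient prior: ", prior$distribution))
}

run_glmm_chains <- function(y, X, groups, group_names, sigma_hn_sd,
                            beta_priors, phi_prior, chains, iter, warmup,
                            seed) {
  init_beta <- numeric(ncol(X))
  exp_rows <- which(beta_priors[, 1] == 2)
  init_beta[exp_rows] <- 0.5
  draws <- vector("list", chains)
  for (c in seq_len(chains)) {
    set.seed(seed + c - 1L)
    draws[[c]] <- cpp_fit_beta_glmm(y, X, groups, sigma_hn_sd, beta_priors,
                                    phi_prior$pars[1], phi_prior$pars[2],
                                    iter, warmup, init_beta, 0.1)
  }
  m <- do.call(rbind, draws)
  nm <- c(paste0("b_", colnames(X)),
          unlist(lapply(seq_along(groups), function(k)
            sprintf("u_%s[%d]", group_names[k], seq_len(max(groups[[k]]))))),
          paste0("sigma_", group_names), "phi")
  colnames(m) <- nm
  list(draws = m, chain = rep(seq_len(chains), each = iter - warmup))
}

finish_fit <- function(draws, chain, spec, model_data, seed, chains, iter,
                       warmup) {
  fit <- structure(list(draws = draws, chain = chain, spec = spec,
                        model_data = model_data, seed = seed,
                        chains = chains, iter = iter, warmup = warmup),
                   class = "lookmix_fit")
  fit$diagnostics <- fit_diagnostics(fit)
  fit
}

refit_loop <- function(runner, spec, model_data, seed, chains, iter, warmup,
                       retries) {
  it <- iter; wu <- warmup
  for (a in seq_len(retries + 1)) {
    res <- runner(it, wu, seed + (a - 1L) * 1000L)
    fit <- finish_fit(res$draws, res$chain, spec, model_data,
                      seed + (a - 1L) * 1000L, chains, it, wu)
    if (fit$diagnostics$converged) return(fit)
    it <- it * 2L; wu <- it %/% 2L
  }
  warning(sprintf("model did not converge (max split-R-hat %.3f) after %d attempt(s)",
                  fit$diagnostics$max_rhat, retries + 1))
  fit
}

#' @rdname fit_model
#' @export
fit_model.graded_spec <- function(spec, data, chains = 4, iter = 2000,
                                  warmup = floor(iter / 2), seed = 1,
                                  retries = 1, ...) {
  check_y(data$y)
  X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "intercept"))
  if (spec$covariate == "rt") X <- cbind(X, rt = data$rt_std)
  if (spec$covariate == "verbs") X <- cbind(X, verbs = data$verbs_std)
  participant <- match(data$participant_id, sort(unique(data$participant_id)))
  beta_priors <- rbind(prior_row(spec$intercept_prior))
  if (ncol(X) > 1) beta_priors <- rbind(beta_priors, prior_row(spec$slope_prior))
  model_data <- list(y = data$y, X = X, groups = list(participant = participant),
                     data = data)
  runner <- function(it, wu, sd)
    run_glmm_chains(data$y, X, list(participant), "participant",
                    spec$sigma_prior$pars[1], beta_priors, spec$phi_prior,
                    chains, it, wu, sd)
  refit_loop(runner, spec, model_data, seed, chains, iter, warmup, retries)
}

#' @rdname fit_model
#' @export
fit_model.chance_spec <- function(spec, data, chains = 4, iter = 2000,
                                  warmup = floor(iter / 2), seed = 1,
                                  retries = 1, ...) {
  check_y(data$y)
  dm <- build_design_matrix(data, spec)
  groups <- list(dm$participant)
  group_names <- "participant"
  if (!is.null(dm$item)) {
    groups <- c(groups, list(dm$item))
    group_names <- c(group_names, "item")
  }
  beta_priors <- rbind(prior_row(spec$intercept_prior))
  if (ncol(dm$X) > 1)
    for (j in 2:ncol(dm$X))
      beta_priors <- rbind(beta_priors, prior_row(spec$coef_prior))
  model_data <- list(y = data$y, X = dm$X, groups = stats::setNames(groups, group_names),
                     data = data)
  runner <- function(it, wu, sd)
    run_glmm_chains(data$y, dm$X, groups, group_names,
                    rep(spec$sigma_prior$pars[1], length(groups)),
                    beta_priors, spec$phi_prior, chains, it, wu, sd)
  refit_loop(runner, spec, model_data, seed, chains, iter, warmup, retries)
}

#' @rdname fit_model
#' @export
fit_model.discrete_spec <- function(spec, data, chains = 4, iter = 2000,
                                    warmup = floor(iter / 2), seed = 1,
                                    retries = 1, ...) {
  check_y(data$y)
  participant <- match(data$participant_id, sort(unique(data$participant_id)))
  n_pid <- max(participant)
  placement <- switch(spec$placement, none = 0L, mu2_rt = 1L, pi_verbs = 2L)
  per_pid <- function(col) {
    if (!col %in% names(data)) return(numeric(n_pid))
    as.numeric(tapply(data[[col]], participant, function(v) v[1]))
  }
  x_mu2 <- if (placement == 1L) per_pid("rt_std") else numeric(n_pid)
  x_pi <- if (placement == 2L) per_pid("verbs_std") else numeric(n_pid)
  if (placement == 1L && !"rt_std" %in% names(data))
    stop("placement mu2_rt needs an rt_std column")
  if (placement == 2L && !"verbs_std" %in% names(data))
    stop("placement pi_verbs needs a verbs_std column")
  prior_pars <- c(spec$mu1_prior$pars, spec$mu2_prior$pars,
                  spec$phi_prior$pars, spec$slope_prior$pars[2],
                  spec$pi_intercept_prior$pars[2], spec$slope_prior$pars[2])
  nm <- c("mu1_logit", "mu2_logit", "log_phi1", "log_phi2",
          switch(spec$placement,
                 none = "pi_logit",
                 mu2_rt = c("b_rt", "pi_logit"),
                 pi_verbs = c("b0_pi", "b_verbs")))
  # data-driven initialization: component 2 starts at the upper-quartile
  # logit so chains begin near the separated-mixture mode rather than the
  # one-broad-component local mode
  q75 <- stats::quantile(data$y, 0.75, names = FALSE)
  init <- c(spec$mu1_prior$pars[1],
            stats::qlogis(min(max(q75, 0.55), 0.9)),
            log(15), log(15),
            switch(spec$placement, none = 0, mu2_rt = c(0, 0),
                   pi_verbs = c(0, 0)))
  runner <- function(it, wu, sd) {
    draws <- vector("list", chains)
    for (c in seq_len(chains)) {
      set.seed(sd + c - 1L)
      draws[[c]] <- cpp_fit_beta_mixture(data$y, participant, n_pid, x_mu2,
                                         x_pi, placement, prior_pars, init,
                                         it, wu, 0.1)
    }
    m <- do.call(rbind, draws)
    colnames(m) <- nm
    m[, "log_phi1"] <- exp(m[, "log_phi1"])
    m[, "log_phi2"] <- exp(m[, "log_phi2"])
    colnames(m)[3:4] <- c("phi1", "phi2")
    list(draws = m, chain = rep(seq_len(chains), each = it - wu))
  }
  model_data <- list(y = data$y, participant = participant, n_pid = n_pid,
                     x_mu2 = x_mu2, x_pi = x_pi, placement = placement,
                     data = data)
  refit_loop(runner, spec, model_data, seed, chains, iter, warmup, retries)
}

#' @export
print.lookmix_fit <- function(x, ...) {
  cat("<lookmix_fit> ", x$spec$model, " model: ",
      nrow(x$draws), " draws (", x$chains, " chains x ",
      x$iter - x$warmup, " kept)\n", sep = "")
  cat("max split-R-hat: ", round(x$diagnostics$max_rhat, 4),
      if (x$diagnostics$converged) " (converged)\n" else " (NOT converged)\n",
      sep = "")
  invisible(x)
}

mixture_pi_draws <- function(fit) {
  d <- fit$draws
  if (fit$model_data$placement == 2L)
    stop("membership probability is participant-specific under pi_verbs")
  stats::plogis(d[, "pi_logit"])
}
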