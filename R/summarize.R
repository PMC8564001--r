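#' Posterior summaries on the logit and probability scales
#'
#' Summarizes one or more parameters: posterior mean, equal-tailed 95%
#' credible interval, and the posterior probability of direction (mass
#' above 0, matching how "posterior probability" is reported for
#' logit-scale coefficients). For logit-scale location parameters the
#' probability-scale summary applies the inverse logit to every draw and
#' then summarizes (never the inverse logit of the summary).
#'
#' @param fit a `lookmix_fit` (or a draws matrix with named columns).
#' @param pars parameter names; default all non-random-effect parameters.
#' @param prob interval mass (default 0.95).
#' @param prob_scale parameter names to additionally summarize on the
#'   probability scale; defaults to logit-scale location parameters
#'   (intercepts and component means).
#' @return data.frame with columns `parameter`, `mean`, `ci_low`,
#'   `ci_high`, `prob_direction`, `p_mean`, `p_ci_low`, `p_ci_high` (the
#'   `p_*` columns are `NA` for parameters not on the probability scale).
#' @export
summarize_fit <- function(fit, pars = NULL, prob = 0.95, prob_scale = NULL) {
  draws <- if (inherits(fit, "lookmix_fit")) fit$draws else fit
  if (is.null(pars))
    pars <- grep("^u_", colnames(draws), value = TRUE, invert = TRUE)
  missing_pars <- setdiff(pars, colnames(draws))
  if (length(missing_pars))
    stop("unknown parameter(s): ", paste(missing_pars, collapse = ", "))
  if (is.null(prob_scale))
    prob_scale <- intersect(pars, c("b_intercept", "mu1_logit", "mu2_logit",
                                    "pi_logit"))
  a <- (1 - prob) / 2
  out <- do.call(rbind, lapply(pars, function(p) {
    x <- draws[, p]
    q <- stats::quantile(x, c(a, 1 - a), names = FALSE)
    r <- data.frame(parameter = p, mean = mean(x), ci_low = q[1],
                    ci_high = q[2], prob_direction = mean(x > 0),
                    p_mean = NA_real_, p_ci_low = NA_real_,
                    p_ci_high = NA_real_, stringsAsFactors = FALSE)
    if (p %in% prob_scale) {
      px <- stats::plogis(x)
      pq <- stats::quantile(px, c(a, 1 - a), names = FALSE)
      r$p_mean <- mean(px); r$p_ci_low <- pq[1]; r$p_ci_high <- pq[2]
    }
    r
  }))
  rownames(out) <- NULL
  out
}

#' Pointwise log-likelihood matrix
#'
#' Computes the draws-by-observations log-likelihood matrix needed for
#' PSIS-LOO. For mixed (GLMM) models, `type = "conditional"` conditions
#' on the sampled random intercepts (one column per observation);
#' `type = "marginal"` integrates the participant intercept out by
#' Gauss-Hermite quadrature and returns one column per participant,
#' which puts the mixed model on the same footing as the mixture (whose
#' membership label is always marginalized). With one observation per
#' participant - the design of the graded-vs-discrete comparison - the
#' marginal type is the defensible choice and is what the packaged model
#' comparisons use.
#'
#' @param fit a `lookmix_fit`.
#' @param type `"conditional"` or `"marginal"` (GLMM fits only).
#' @param gh_points quadrature points for the marginal type.
#' @return matrix (draws x observations or draws x participants).
#' @export
log_lik_matrix <- function(fit, type = c("conditional", "marginal"),
                           gh_points = 21) {
  type <- match.arg(type)
  d <- fit$draws
  md <- fit$model_data
  if (fit$spec$model == "discrete") {
    return(mixture_log_lik(fit))
  }
  X <- md$X
  bcols <- paste0("b_", colnames(X))
  B <- d[, bcols, drop = FALSE]
  eta_fix <- B %*% t(X)  # S x n
  phi <- d[, "phi"]
  if (type == "conditional") {
    eta <- eta_fix
    for (k in seq_along(md$groups)) {
      gname <- names(md$groups)[k]
      U <- d[, grep(sprintf("^u_%s\\[", gname), colnames(d)), drop = FALSE]
      eta <- eta + U[, md$groups[[k]], drop = FALSE]
    }
    mu <- stats::plogis(eta)
    Y <- matrix(md$y, nrow(d), length(md$y), byrow = TRUE)
    return(matrix(stats::dbeta(Y, mu * phi, (1 - mu) * phi, log = TRUE),
                  nrow(d), length(md$y)))
  }
  if (length(md$groups) != 1 || names(md$groups) != "participant")
    stop("marginal log-lik implemented for participant-only grouping")
  g <- md$groups$participant
  n_pid <- max(g)
  # fixed-effect linear predictor per participant (covariates are
  # participant-level in the graded models)
  first <- match(seq_len(n_pid), g)
  eta_pid <- eta_fix[, first, drop = FALSE]
  gh <- gauss_hermite(gh_points)
  cpp_graded_marginal_loglik(md$y, g, n_pid, eta_pid,
                             d[, "sigma_participant"], phi,
                             gh$nodes, log(gh$weights))
}

mixture_log_lik <- function(fit) {
  d <- fit$draws
  md <- fit$model_data
  S <- nrow(d)
  n_pid <- md$n_pid
  mu1 <- stats::plogis(d[, "mu1_logit"])
  phi1 <- d[, "phi1"]; phi2 <- d[, "phi2"]
  out <- matrix(NA_real_, S, n_pid)
  pid <- md$participant
  for (g in seq_len(n_pid)) {
    yg <- md$y[pid == g]
    lp1 <- rowSums(vapply(yg, function(yy)
      stats::dbeta(yy, mu1 * phi1, (1 - mu1) * phi1, log = TRUE),
      numeric(S)))
    mu2 <- if (md$placement == 1L)
      stats::plogis(d[, "mu2_logit"] + d[, "b_rt"] * md$x_mu2[g])
    else stats::plogis(d[, "mu2_logit"])
    lp2 <- rowSums(vapply(yg, function(yy)
      stats::dbeta(yy, mu2 * phi2, (1 - mu2) * phi2, log = TRUE),
      numeric(S)))
    lpi <- if (md$placement == 2L)
      d[, "b0_pi"] + d[, "b_verbs"] * md$x_pi[g]
    else d[, "pi_logit"]
    lse <- ifelse(lpi > 0, lpi + log1p(exp(-lpi)), log1p(exp(lpi)))
    A <- -lse + lp1          # log(1-pi) + lp1
    B <- (lpi - lse) + lp2   # log(pi) + lp2
    mx <- pmax(A, B)
    out[, g] <- mx + log(exp(A - mx) + exp(B - mx))
  }
  out
}

#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights for integrals against `exp(-x^2)` (Golub-Welsch, via
#' the symmetric tridiagonal Jacobi matrix).
#'
#' @param n number of points.
#' @return list with `nodes` and `weights`.
#' @export
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * e$vectors[1, ord]^2)
}

#' Model-implied condition means
#'
#' For a chance-level model with factors, computes the posterior
#' distribution of the cell means on the probability scale with the
#' salience covariate at 0 and random effects at the population level
#' (set to zero).
#'
#' @param fit a `lookmix_fit` of a [chance_spec()] with factors.
#' @param conditions data.frame of cells (`window`, `trial`, optionally
#'   `bin`); defaults to the full factorial grid.
#' @return data.frame with one row per cell: posterior mean and 95% CI
#'   of the cell mean on the probability scale.
#' @export
condition_means <- function(fit, conditions = NULL) {
  spec <- fit$spec
  if (spec$model != "chance") stop("condition_means needs a chance-model fit")
  if (is.null(conditions)) {
    conditions <- expand.grid(window = 1:2, trial = 1:2)
    if (spec$factors == "window_trial_bin")
      conditions <- expand.grid(window = 1:2, trial = 1:2, bin = 1:4)
  }
  bad <- (!all(conditions$window %in% 1:2)) || (!all(conditions$trial %in% 1:2))
  if (isTRUE(bad)) stop("condition outside the design")
  cells <- conditions
  cells$participant_id <- 1
  cells$sequence_id <- 1
  cells$salience_logit <- 0
  spec_noitem <- spec
  spec_noitem$re_item <- FALSE
  dm <- build_design_matrix(cells, spec_noitem)
  bcols <- paste0("b_", colnames(dm$X))
  eta <- fit$draws[, bcols, drop = FALSE] %*% t(dm$X)
  p <- stats::plogis(eta)
  out <- conditions
  out$mean <- colMeans(p)
  qs <- apply(p, 2, stats::quantile, probs = c(0.025, 0.975))
  out$ci_low <- qs[1, ]; out$ci_high <- qs[2, ]
  out
}
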