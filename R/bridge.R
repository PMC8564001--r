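#' Marginal likelihood by bridge sampling
#'
#' Implements the iterative (optimal) bridge estimator of the marginal
#' likelihood from posterior draws plus a moment-matched multivariate
#' normal proposal on the unconstrained parameter space. The posterior
#' sample is split in half: the first half fits the proposal, the second
#' enters the bridge identity, which is iterated in log space to a
#' relative tolerance of 1e-10 (at most 1000 iterations). The Monte Carlo
#' error estimate treats the bridge terms as independent draws (a
#' simplification of the spectral formula; adequate for the
#' well-separated toy and model comparisons used here).
#'
#' @param samples matrix of posterior draws on the *unconstrained* scale
#'   (rows = draws). For fitted models use [unconstrain_draws()].
#' @param log_joint function taking one unconstrained parameter vector
#'   and returning the log joint density (log prior + log likelihood +
#'   log Jacobians of the unconstraining transform).
#' @param n_proposal proposal draws (default: size of the bridge half).
#' @param tol,max_iter iteration control.
#' @return list with `log_ml`, `mc_error_estimate`, `n_bridge_iterations`,
#'   `converged`.
#' @export
bridge_logml <- function(samples, log_joint, n_proposal = NULL,
                         tol = 1e-10, max_iter = 1000) {
  samples <- as.matrix(samples)
  N <- nrow(samples); D <- ncol(samples)
  if (N < 10) stop("too few posterior draws for bridge sampling")
  half1 <- samples[seq(1, N, by = 2), , drop = FALSE]
  half2 <- samples[seq(2, N, by = 2), , drop = FALSE]
  m <- colMeans(half1)
  V <- stats::cov(half1)
  V <- V + diag(1e-10 + 1e-8 * mean(diag(V)), D)
  ch <- chol(V)
  if (is.null(n_proposal)) n_proposal <- nrow(half2)
  Z <- matrix(stats::rnorm(n_proposal * D), n_proposal, D)
  prop <- Z %*% ch + matrix(m, n_proposal, D, byrow = TRUE)

  log_g <- function(X) {
    # multivariate normal log density
    dif <- X - matrix(m, nrow(X), D, byrow = TRUE)
    sol <- t(backsolve(ch, t(dif), transpose = TRUE))
    -0.5 * rowSums(sol^2) - sum(log(diag(ch))) - 0.5 * D * log(2 * pi)
  }
  eval_lj <- function(X) apply(X, 1, log_joint)

  l1 <- eval_lj(half2) - log_g(half2)   # at posterior draws
  l2 <- eval_lj(prop) - log_g(prop)     # at proposal draws
  keep <- is.finite(l2)
  l2 <- l2[keep]
  if (length(l2) < 10) stop("proposal degenerate: log joint not finite")
  N1 <- length(l1); N2 <- length(l2)
  s1 <- N1 / (N1 + N2); s2 <- N2 / (N1 + N2)
  lstar <- stats::median(l1)
  lse <- function(v) { mx <- max(v); mx + log(sum(exp(v - mx))) }
  log_r <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # numerator: mean over proposal draws of exp(l2*)/(s1 exp(l2*) + s2 r)
    den2 <- pmax(log(s1) + (l2 - lstar),
                 log(s2) + log_r) +
      log1p(exp(-abs((log(s1) + (l2 - lstar)) - (log(s2) + log_r))))
    log_num <- lse((l2 - lstar) - den2) - log(N2)
    den1 <- pmax(log(s1) + (l1 - lstar), log(s2) + log_r) +
      log1p(exp(-abs((log(s1) + (l1 - lstar)) - (log(s2) + log_r))))
    log_den <- lse(-den1) - log(N1)
    log_r_new <- log_num - log_den
    if (is.finite(log_r_new) && abs(log_r_new - log_r) <
        tol * max(1, abs(log_r_new))) {
      log_r <- log_r_new; converged <- TRUE
      break
    }
    log_r <- log_r_new
  }
  # iid-draw approximation to the relative MC error
  f1 <- exp((l2 - lstar) - den2)
  f2 <- exp(-den1)
  re2 <- stats::var(f1) / (N2 * mean(f1)^2) +
    stats::var(f2) / (N1 * mean(f2)^2)
  list(log_ml = log_r + lstar, mc_error_estimate = sqrt(max(re2, 0)),
       n_bridge_iterations = it, converged = converged)
}

#' Unconstrained draws and log-joint closure for a fitted model
#'
#' Maps the sampled parameters onto an unconstrained space (SDs and
#' precisions to logs; an exponential-prior intercept to its log) and
#' builds the matching log joint (priors + likelihood + Jacobians) so the
#' fit can be fed to [bridge_logml()]. Random intercepts are integrated
#' over as part of the joint (they are columns of the draws), so the
#' resulting marginal likelihood is that of the full hierarchical model.
#'
#' @param fit a `lookmix_fit` of a GLMM-type spec ([chance_spec()] or
#'   [graded_spec()]).
#' @return list with `samples` (matrix) and `log_joint` (function).
#' @export
unconstrain_draws <- function(fit) {
  if (!fit$spec$model %in% c("chance", "graded"))
    stop("unconstrain_draws supports the GLMM-type models")
  d <- fit$draws
  md <- fit$model_data
  X <- md$X; y <- md$y
  p <- ncol(X)
  group_names <- names(md$groups)
  bcols <- paste0("b_", colnames(X))
  priors <- c(list(fit$spec$intercept_prior),
              if (p > 1) rep(list(
                if (fit$spec$model == "chance") fit$spec$coef_prior
                else fit$spec$slope_prior), p - 1))
  exp_intercept <- priors[[1]]$distribution == "exponential"

  samples <- d
  if (exp_intercept) samples[, bcols[1]] <- log(samples[, bcols[1]])
  for (g in group_names) {
    cn <- paste0("sigma_", g)
    samples[, cn] <- log(samples[, cn])
  }
  samples[, "phi"] <- log(samples[, "phi"])

  ucols <- lapply(group_names, function(g)
    grep(sprintf("^u_%s\\[", g), colnames(d)))
  names(ucols) <- group_names
  sigma_hn <- fit$spec$sigma_prior$pars[1]
  phi_prior <- fit$spec$phi_prior

  log_joint <- function(theta) {
    names(theta) <- colnames(samples)
    b <- theta[bcols]
    jac <- 0
    if (exp_intercept) {
      jac <- jac + b[1]       # d b / d log(b)
      b[1] <- exp(b[1])
    }
    lp <- sum(vapply(seq_len(p), function(j)
      prior_logpdf(priors[[j]], b[j]), numeric(1)))
    eta <- as.numeric(X %*% b)
    for (g in group_names) {
      u <- theta[ucols[[g]]]
      ls <- theta[paste0("sigma_", g)]
      sig <- exp(ls)
      lp <- lp + log(2) + stats::dnorm(sig, 0, sigma_hn, log = TRUE) + ls
      lp <- lp + sum(stats::dnorm(u, 0, sig, log = TRUE))
      eta <- eta + u[md$groups[[g]]]
    }
    lphi <- theta[["phi"]]
    phi <- exp(lphi)
    lp <- lp + prior_logpdf(phi_prior, phi) + lphi
    mu <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
    lp + jac + sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  list(samples = samples, log_joint = log_joint)
}

#' Bayes factor from two fitted models
#'
#' Computes marginal likelihoods for a null and an alternative model by
#' bridge sampling and reports `BF = p(y | alt) / p(y | null)`, so values
#' below 1 favor the null. The two fits must share the same data and
#' likelihood, differing only in the intercept prior.
#'
#' @param null_fit,alt_fit `lookmix_fit` objects.
#' @return list with `bf_alt_over_null`, `log_bf`, and the two
#'   [bridge_logml()] results (`null`, `alt`).
#' @export
bayes_factor <- function(null_fit, alt_fit) {
  if (!isTRUE(all.equal(null_fit$model_data$y, alt_fit$model_data$y)))
    stop("fits were not computed on identical data")
  un <- unconstrain_draws(null_fit)
  ua <- unconstrain_draws(alt_fit)
  mln <- bridge_logml(un$samples, un$log_joint)
  mla <- bridge_logml(ua$samples, ua$log_joint)
  log_bf <- mla$log_ml - mln$log_ml
  list(bf_alt_over_null = exp(log_bf), log_bf = log_bf,
       null = mln, alt = mla)
}
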