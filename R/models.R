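#' Model of graded individual differences
#'
#' An intercept-only beta mean-precision regression with Gaussian random
#' intercepts by participant:
#' `Prop_i ~ Beta(mu_i, phi)`, `mu_i = inv_logit(B0 + t_i)`,
#' `t_i ~ Normal(0, sigma)`. Priors: `sigma ~ Normal(0, 1)` truncated to
#' the positive reals (an SD must be positive; implemented as a
#' half-normal), `phi ~ Gamma(3.5, 0.5)` (shape-rate). Optionally a
#' standardized covariate (lexical-processing RT or verb count) enters
#' the mean's linear predictor with a `Normal(0, 1)` slope prior.
#'
#' @param covariate `"none"`, `"rt"` (adds `rt_std`) or `"verbs"` (adds
#'   `verbs_std`) to the mean's linear predictor.
#' @param intercept_prior,slope_prior,sigma_prior,phi_prior [prior_spec()]s.
#' @return object of class `c("graded_spec", "lookmix_spec")`.
#' @export
graded_spec <- function(covariate = c("none", "rt", "verbs"),
                        intercept_prior = prior_spec("student_t", 3, 0, 2.5,
                                                     scale = "logit"),
                        slope_prior = prior_spec("normal", 0, 1,
                                                 scale = "natural"),
                        sigma_prior = prior_spec("half_normal", 1,
                                                 scale = "natural"),
                        phi_prior = prior_spec("gamma", 3.5, 0.5,
                                               scale = "natural")) {
  covariate <- match.arg(covariate)
  structure(list(model = "graded", covariate = covariate,
                 intercept_prior = intercept_prior,
                 slope_prior = slope_prior, sigma_prior = sigma_prior,
                 phi_prior = phi_prior),
            class = c("graded_spec", "lookmix_spec"))
}

#' Model of discrete individual differences
#'
#' A two-component beta mixture:
#' `Prop_i ~ (1 - T_i) * Beta(mu1, phi1) + T_i * Beta(mu2, phi2)`,
#' `T_i ~ Bernoulli(pi)`. Component 1 is anchored at chance by its prior
#' (intercept `Normal(0, 0.05)` on the logit scale, the same prior used
#' as the chance-level null); component 2 is above chance (`Normal(0.4,
#' 0.15)`, the first alternative prior). Both precisions get
#' `Gamma(3.5, 0.5)`. Identifiability is enforced by these asymmetric
#' priors alone; no ordering constraint is imposed. The membership
#' probability has a uniform `Beta(1, 1)` prior.
#'
#' Covariate placements mirror the two tested extensions exactly:
#' `"mu2_rt"` puts standardized RT on the group-2 mean logit,
#' `mu_2i = inv_logit(B0 + B1 * rt_std)`; `"pi_verbs"` puts standardized
#' verb count on the membership logit,
#' `pi_i = inv_logit(B0 + B1 * verbs_std)` (membership intercept
#' `Normal(0, 1.5)`, slope `Normal(0, 1)`).
#'
#' @param placement `"none"`, `"mu2_rt"` or `"pi_verbs"`.
#' @param mu1_prior,mu2_prior,phi_prior,slope_prior,pi_intercept_prior
#'   [prior_spec()]s.
#' @return object of class `c("discrete_spec", "lookmix_spec")`.
#' @export
discrete_spec <- function(placement = c("none", "mu2_rt", "pi_verbs"),
                          mu1_prior = prior_spec("normal", 0, 0.05,
                                                 scale = "logit"),
                          mu2_prior = prior_spec("normal", 0.4, 0.15,
                                                 scale = "logit"),
                          phi_prior = prior_spec("gamma", 3.5, 0.5,
                                                 scale = "natural"),
                          slope_prior = prior_spec("normal", 0, 1,
                                                   scale = "natural"),
                          pi_intercept_prior = prior_spec("normal", 0, 1.5,
                                                          scale = "logit")) {
  placement <- match.arg(placement)
  structure(list(model = "discrete", placement = placement,
                 mu1_prior = mu1_prior, mu2_prior = mu2_prior,
                 phi_prior = phi_prior, slope_prior = slope_prior,
                 pi_intercept_prior = pi_intercept_prior),
            class = c("discrete_spec", "lookmix_spec"))
}

#' Chance-level test models
#'
#' Mixed-effects beta regressions asking whether looks to the target
#' exceed chance (logit 0 = proportion 0.5): a fixed intercept, an
#' optional action-salience covariate, optional sum-coded window/trial
#' (and bin) factors with their interactions, and random intercepts by
#' participant and by item (the 16 unique trial types). The intercept
#' prior defaults to a weakly informative Student-t(3, 0, 2.5) on the
#' logit scale; Bayes-factor variants replace it with the null
#' (`Normal(0, 0.05)`) or one of the two alternative priors
#' (`Normal(0.4, 0.15)` or `Exponential(1)`).
#'
#' @param factors `"none"`, `"window_trial"` or `"window_trial_bin"`.
#' @param salience include the salience-logit covariate?
#' @param intercept_prior [prior_spec()] for the fixed intercept.
#' @param coef_prior prior for the non-intercept fixed effects.
#' @param sigma_prior half-normal prior for both random-intercept SDs.
#' @param phi_prior prior for the precision.
#' @param re_item include the by-item random intercept?
#' @return object of class `c("chance_spec", "lookmix_spec")`.
#' @export
chance_spec <- function(factors = c("none", "window_trial",
                                    "window_trial_bin"),
                        salience = FALSE,
                        intercept_prior = prior_spec("student_t", 3, 0, 2.5,
                                                     scale = "logit"),
                        coef_prior = prior_spec("normal", 0, 1,
                                                scale = "natural"),
                        sigma_prior = prior_spec("half_normal", 1,
                                                 scale = "natural"),
                        phi_prior = prior_spec("gamma", 3.5, 0.5,
                                               scale = "natural"),
                        re_item = TRUE) {
  factors <- match.arg(factors)
  structure(list(model = "chance", factors = factors, salience = salience,
                 intercept_prior = intercept_prior, coef_prior = coef_prior,
                 sigma_prior = sigma_prior, phi_prior = phi_prior,
                 re_item = re_item),
            class = c("chance_spec", "lookmix_spec"))
}

#' Design matrix for the chance-level tests
#'
#' Window and trial are sum coded with level 1 at +0.5 and level 2 at
#' -0.5; interaction columns are products of the codes. Bin (4 levels,
#' 2000-ms bins) uses sum-to-zero contrasts scaled to +-0.5 on the first
#' three levels. The item index is derived from (sequence, trial), giving
#' 16 levels.
#'
#' @param observations data.frame with (depending on `spec`) columns
#'   `window`, `trial`, `bin`, `salience_logit`, `participant_id`,
#'   `sequence_id`.
#' @param spec a [chance_spec()].
#' @return list with `X` (model matrix, intercept first), `participant`
#'   (1-based index), `item` (1-based index or `NULL`).
#' @export
build_design_matrix <- function(observations, spec) {
  n <- nrow(observations)
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if (spec$salience) {
    if (!"salience_logit" %in% names(observations))
      stop("salience covariate requested but salience_logit missing")
    X <- cbind(X, salience = observations$salience_logit)
  }
  code2 <- function(x, name) {
    if (!all(x %in% 1:2)) stop(sprintf("unknown %s level", name))
    ifelse(x == 1, 0.5, -0.5)
  }
  if (spec$factors != "none") {
    wcol <- code2(observations$window, "window")
    tcol <- code2(observations$trial, "trial")
    X <- cbind(X, window = wcol, trial = tcol, `window:trial` = wcol * tcol)
    if (spec$factors == "window_trial_bin") {
      if (!all(observations$bin %in% 1:4)) stop("unknown bin level")
      B <- stats::contr.sum(4)[observations$bin, , drop = FALSE] / 2
      colnames(B) <- paste0("bin", 1:3)
      inter <- cbind(wcol * B, tcol * B, wcol * tcol * B)
      colnames(inter) <- c(paste0("window:bin", 1:3),
                           paste0("trial:bin", 1:3),
                           paste0("window:trial:bin", 1:3))
      X <- cbind(X, B, inter)
    }
  }
  participant <- match(observations$participant_id,
                       sort(unique(observations$participant_id)))
  item <- NULL
  if (isTRUE(spec$re_item)) {
    if (!all(c("sequence_id", "trial") %in% names(observations)))
      stop("item random effect needs sequence_id and trial columns")
    item_id <- (observations$sequence_id - 1L) * 2L + observations$trial
    item <- match(item_id, sort(unique(item_id)))
  }
  list(X = X, participant = participant, item = item)
}

#' The registry of fitted model specifications
#'
#' All model specifications used in the analysis pipeline, with their
#' exact priors:
#' * `chance`, `chance_salience`: intercept-only mixed beta regressions
#'   (random intercepts by participant and item), without/with the
#'   action-salience covariate.
#' * `window_trial`, `window_trial_bin`: sum-coded factorial extensions.
#' * `bf_null`, `bf_alt1`, `bf_alt2`: the chance model with intercept
#'   prior Normal(0, 0.05), Normal(0.4, 0.15), Exponential(1) - the
#'   null and the two alternative hypotheses compared by Bayes factor.
#' * `graded`, `graded_rt`, `graded_verbs`: random-intercept models with
#'   `sigma ~ half-Normal(0, 1)`, `phi ~ Gamma(3.5, 0.5)`.
#' * `discrete`, `discrete_rt`, `discrete_verbs`: two-component mixtures;
#'   the RT covariate acts on the group-2 mean only, the verb covariate
#'   on the membership probability only.
#'
#' @return named list of specification objects.
#' @export
model_registry <- function() {
  list(
    chance = chance_spec("none"),
    chance_salience = chance_spec("none", salience = TRUE),
    window_trial = chance_spec("window_trial", salience = TRUE),
    window_trial_bin = chance_spec("window_trial_bin", salience = TRUE),
    bf_null = chance_spec("none",
      intercept_prior = prior_spec("normal", 0, 0.05, scale = "logit")),
    bf_alt1 = chance_spec("none",
      intercept_prior = prior_spec("normal", 0.4, 0.15, scale = "logit")),
    bf_alt2 = chance_spec("none",
      intercept_prior = prior_spec("exponential", 1, scale = "logit")),
    graded = graded_spec("none"),
    graded_rt = graded_spec("rt"),
    graded_verbs = graded_spec("verbs"),
    discrete = discrete_spec("none"),
    discrete_rt = discrete_spec("mu2_rt"),
    discrete_verbs = discrete_spec("pi_verbs")
  )
}

#' @export
format.lookmix_spec <- function(x, ...) {
  pr <- vapply(x[vapply(x, inherits, TRUE, what = "prior_spec")],
               format, character(1))
  hdr <- switch(x$model,
    graded = sprintf("graded mixed model (covariate: %s)", x$covariate),
    discrete = sprintf("discrete two-component mixture (placement: %s)",
                       x$placement),
    chance = sprintf("chance-level mixed model (factors: %s, salience: %s)",
                     x$factors, x$salience))
  paste0(hdr, "\n", paste(sprintf("  %s ~ %s", names(pr), pr),
                          collapse = "\n"))
}

#' @export
print.lookmix_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Serialize the model registry as text
#'
#' One self-describing block per model (likelihood, linear predictors,
#' priors), so reports can echo exactly what was fitted.
#'
#' @param models named list from [model_registry()].
#' @return character scalar.
#' @export
model_registry_text <- function(models = model_registry()) {
  paste(vapply(names(models), function(nm)
    paste0("[", nm, "]\n", format(models[[nm]])), character(1)),
    collapse = "\n\n")
}
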