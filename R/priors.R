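#' Prior specifications
#'
#' A `prior_spec` names a univariate prior distribution together with the
#' scale it lives on. Intercept priors in the chance-level tests live on
#' the logit scale, so their implied beliefs about the proportion of looks
#' to the target are read off by pushing quantiles through the inverse
#' logit (see [prior_interval()]).
#'
#' Supported distributions:
#' * `normal(mean, sd)`
#' * `gamma(shape, rate)` (shape-rate convention)
#' * `exponential(rate)`
#' * `half_normal(sd)` (a Normal(0, sd) truncated to the positive reals)
#' * `student_t(df, mean, scale)`
#'
#' @param distribution one of `"normal"`, `"gamma"`, `"exponential"`,
#'   `"half_normal"`, `"student_t"`.
#' @param ... distribution parameters, in the order listed above.
#' @param applies_to optional parameter name the prior is attached to.
#' @param scale `"logit"` or `"natural"`.
#' @return an object of class `prior_spec`.
#' @examples
#' prior_spec("normal", 0, 0.05, scale = "logit")  # the chance-level null
#' @export
prior_spec <- function(distribution, ..., applies_to = NULL,
                       scale = c("logit", "natural")) {
  distribution <- match.arg(distribution, c("normal", "gamma", "exponential",
                                            "half_normal", "student_t"))
  pars <- as.numeric(c(...))
  n_expected <- switch(distribution,
                       normal = 2L, gamma = 2L, exponential = 1L,
                       half_normal = 1L, student_t = 3L)
  if (length(pars) != n_expected)
    stop(sprintf("'%s' expects %d parameter(s)", distribution, n_expected))
  pos <- switch(distribution,
                normal = pars[2], gamma = pars, exponential = pars,
                half_normal = pars, student_t = pars[c(1, 3)])
  if (any(pos <= 0)) stop("scale/shape/rate parameters must be positive")
  structure(list(distribution = distribution, pars = pars,
                 applies_to = applies_to, scale = match.arg(scale)),
            class = "prior_spec")
}

#' @export
format.prior_spec <- function(x, ...) {
  sprintf("%s(%s)%s", x$distribution, paste(x$pars, collapse = ", "),
          if (is.null(x$applies_to)) "" else paste0(" on ", x$applies_to))
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("<prior_spec> ", format(x), " [", x$scale, " scale]\n", sep = "")
  invisible(x)
}

prior_quantile <- function(prior, p) {
  with(prior, switch(distribution,
    normal      = stats::qnorm(p, pars[1], pars[2]),
    gamma       = stats::qgamma(p, shape = pars[1], rate = pars[2]),
    exponential = stats::qexp(p, rate = pars[1]),
    half_normal = stats::qnorm(0.5 + p / 2, 0, pars[1]),
    student_t   = pars[2] + pars[3] * stats::qt(p, df = pars[1])
  ))
}

prior_logpdf <- function(prior, x) {
  with(prior, switch(distribution,
    normal      = stats::dnorm(x, pars[1], pars[2], log = TRUE),
    gamma       = stats::dgamma(x, shape = pars[1], rate = pars[2], log = TRUE),
    exponential = stats::dexp(x, rate = pars[1], log = TRUE),
    half_normal = ifelse(x < 0, -Inf,
                         log(2) + stats::dnorm(x, 0, pars[1], log = TRUE)),
    student_t   = stats::dt((x - pars[2]) / pars[3], df = pars[1], log = TRUE) -
                  log(pars[3])
  ))
}

prior_draw <- function(prior, n) {
  with(prior, switch(distribution,
    normal      = stats::rnorm(n, pars[1], pars[2]),
    gamma       = stats::rgamma(n, shape = pars[1], rate = pars[2]),
    exponential = stats::rexp(n, rate = pars[1]),
    half_normal = abs(stats::rnorm(n, 0, pars[1])),
    student_t   = pars[2] + pars[3] * stats::rt(n, df = pars[1])
  ))
}

#' Probability-scale interval implied by a logit-scale prior
#'
#' Pushes the equal-tailed quantiles of a prior on the logit scale through
#' the inverse-logit. Because the inverse logit is strictly monotone, the
#' endpoints are exactly the quantiles of the induced distribution on the
#' probability scale. With the chance-level null prior Normal(0, 0.05)
#' this gives a 95% interval of (0.48, 0.52) after rounding: the belief
#' that looking is essentially at chance.
#'
#' @param prior a [prior_spec()] with `scale = "logit"`.
#' @param level interval mass, in (0, 1); default 0.95 equal-tailed.
#' @return named numeric vector `c(low = , high = )` on the probability scale.
#' @export
prior_interval <- function(prior, level = 0.95) {
  stopifnot(inherits(prior, "prior_spec"))
  if (prior$scale != "logit")
    stop("prior_interval expects a prior on the logit scale")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  alpha <- (1 - level) / 2
  q <- prior_quantile(prior, c(alpha, 1 - alpha))
  stats::setNames(stats::plogis(q), c("low", "high"))
}
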