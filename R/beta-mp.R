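#' Mean-precision parameterization of the beta distribution
#'
#' The models in this package describe proportions of looks to a target
#' video with a beta likelihood parameterized by a mean `mu` in (0, 1) and
#' a precision `phi > 0`. The usual shape parameters are recovered as
#' `a = mu * phi`, `b = (1 - mu) * phi`, and the variance is
#' `mu * (1 - mu) / (1 + phi)`, so larger `phi` means tighter data around
#' the mean at any given central tendency.
#'
#' @param y numeric vector of proportions strictly inside (0, 1).
#' @param mu mean(s) in (0, 1).
#' @param phi precision(s), positive.
#' @param log logical; return log density?
#' @return `dbeta_mp` returns (log) densities; `rbeta_mp` returns draws;
#'   `beta_mp_shapes` a list with `shape1`, `shape2`; `beta_mp_var` the
#'   variance implied by (`mu`, `phi`).
#' @examples
#' dbeta_mp(0.5, mu = 0.5, phi = 2)        # Beta(1, 1): density 1
#' beta_mp_var(0.5, 22.7)                  # ~0.0105, SD ~0.10
#' @export
dbeta_mp <- function(y, mu, phi, log = FALSE) {
  stopifnot(all(phi > 0), all(mu > 0 & mu < 1))
  if (any(y <= 0 | y >= 1)) stop("y must lie strictly inside (0, 1)")
  stats::dbeta(y, shape1 = mu * phi, shape2 = (1 - mu) * phi, log = log)
}

#' @rdname dbeta_mp
#' @param n number of draws.
#' @export
rbeta_mp <- function(n, mu, phi) {
  stopifnot(all(phi > 0), all(mu > 0 & mu < 1))
  stats::rbeta(n, shape1 = mu * phi, shape2 = (1 - mu) * phi)
}

#' @rdname dbeta_mp
#' @export
beta_mp_shapes <- function(mu, phi) {
  stopifnot(all(phi > 0), all(mu > 0 & mu < 1))
  list(shape1 = mu * phi, shape2 = (1 - mu) * phi)
}

#' @rdname dbeta_mp
#' @export
beta_mp_var <- function(mu, phi) mu * (1 - mu) / (1 + phi)

#' Log-likelihood of a two-component beta mixture
#'
#' Computes `log[(1 - pi) * Beta(y; mu1, phi1) + pi * Beta(y; mu2, phi2)]`
#' stably via log-sum-exp. This is the observation-level likelihood of the
#' discrete-individual-differences model, with component 1 anchored at
#' chance and component 2 above chance.
#'
#' @param y proportions in (0, 1).
#' @param mu1,mu2 component means in (0, 1) (probability scale).
#' @param phi1,phi2 component precisions.
#' @param pi_mix membership probability of component 2, in \[0, 1\].
#' @return numeric vector of log-likelihood contributions.
#' @export
mixture_loglik <- function(y, mu1, mu2, phi1, phi2, pi_mix) {
  if (any(pi_mix < 0 | pi_mix > 1)) stop("pi_mix must lie in [0, 1]")
  l1 <- dbeta_mp(y, mu1, phi1, log = TRUE)
  l2 <- dbeta_mp(y, mu2, phi2, log = TRUE)
  if (length(pi_mix) == 1L) pi_mix <- rep(pi_mix, length(l1))
  out <- numeric(length(l1))
  z <- pi_mix == 0
  o <- pi_mix == 1
  out[z] <- l1[z]
  out[o] <- l2[o]
  m <- !z & !o
  a <- log1p(-pi_mix[m]) + l1[m]
  b <- log(pi_mix[m]) + l2[m]
  mx <- pmax(a, b)
  out[m] <- mx + log(exp(a - mx) + exp(b - mx))
  out
}

#' Inverse logit and logit
#'
#' Thin wrappers around [stats::plogis()] / [stats::qlogis()] used
#' throughout; exported because the gap between the logit and probability
#' scales is central to how the models are reported.
#'
#' @param x numeric.
#' @export
inv_logit <- function(x) stats::plogis(x)

#' @rdname inv_logit
#' @export
logit <- function(x) stats::qlogis(x)
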