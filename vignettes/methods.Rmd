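---
title: "Models and methods: graded versus discrete individual differences in preferential looking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

In the intermodal preferential looking (IMPL) paradigm a toddler hears a
transitive sentence with a novel verb while two videos of novel causal
actions, with opposite participant roles, play side by side. The
proportion of valid 60 Hz gaze samples on the sentence-matching video is
the measure of comprehension. Two questions structure the analysis this
package implements:

1. Do children look at the target above chance (proportion 0.5), overall
   and within particular 8-s windows, trials, and 2000-ms bins?
2. Is between-child variation *graded* (every child has their own mean
   looking propensity) or *discrete* (a chance-level group and an
   above-chance group), and is it predicted by verb vocabulary or by
   lexical-processing speed?

Question 2 is a model-comparison problem: graded variation corresponds
to a beta mixed model with Gaussian random intercepts on the logit
scale; discrete variation corresponds to a two-component beta mixture.

## Likelihood and priors

Every model uses the beta distribution in mean–precision form: shapes
`(mu*phi, (1-mu)*phi)`, variance `mu*(1-mu)/(1+phi)`. The beta
likelihood respects the (0, 1) support of proportions and shrinks the
variance near the floor and ceiling without tying it rigidly to the
mean. (An informal description of the variance as "a product of the two
parameters" is sometimes seen; this package uses the standard identity
above throughout.)

Priors, with their rationales:

* **Chance-level null**: intercept `Normal(0, 0.05)` on the logit scale,
  i.e. a 95% belief that the true proportion lies in (0.48, 0.52).
* **Alternative 1**: `Normal(0.4, 0.15)`, consistent with published
  sample means for this task. Note an interval-convention wrinkle: the
  2.5–97.5% quantiles of this prior map to proportions (0.53, 0.67),
  while the 5–95% quantiles map to (0.54, 0.66); published descriptions
  of this prior match the latter, whereas the (0.48, 0.52) claim for the
  null matches the former. `prior_interval()` computes equal-tailed
  intervals at any level, so both conventions are available; the package
  does not guess which was intended.
* **Alternative 2**: `Exponential(1)` on the intercept (positive
  support), spreading mass over proportions from roughly 0.51 upward.
* **Random-intercept SD**: `Normal(0, 1)` truncated to the positive
  reals, i.e. a half-normal. The untruncated form sometimes written for
  an SD parameter is not a valid prior for a scale; truncation at zero
  is the standard reading and changes nothing else.
* **Precision(s)**: `Gamma(3.5, 0.5)` interpreted as **shape–rate**
  (mean 7, SD ~3.7), the convention of the estimation framework this
  parameterization comes from. This prior places very little mass above
  phi ~ 25; the consequences for what the mixture can represent are
  discussed below.
* **Mixture membership**: uniform `Beta(1, 1)` on pi (the source
  analysis is silent); for the covariate-on-membership variant, the
  membership intercept gets `Normal(0, 1.5)` and the slope
  `Normal(0, 1)` — weakly informative defaults echoed in every report.
* **Component means**: the mixture's group-1 mean reuses the
  chance-level null prior and its group-2 mean reuses alternative 1.
  ("The same priors as the Bayes-factor analysis" does not pick between
  the two alternatives; alternative 1 is the package default and is
  configurable.) These asymmetric priors are the only identification
  device — no ordering constraint is imposed — and a label-switching
  check is available post hoc via the chain-agreement diagnostics.
* **First chance-test model**: the original analysis used its software's
  default priors, which are version-dependent; this package substitutes
  a documented weakly informative `Student-t(3, 0, 2.5)` intercept
  prior.

## Estimation

No probabilistic-programming backend is available in the target
environment, so the package ships its own MCMC: univariate
slice-within-Gibbs sampling (stepping-out plus shrinkage) implemented in
C++. Slice sampling is tuning-free, has no divergence pathologies, and
for these models mixes well because random intercepts condition only on
their own participant's (or item's) observations. Defaults are 4 chains
of 2000 iterations (half warmup); the packaged experiments run 2 chains
of 800 as documented. Convergence is monitored with split-R-hat (fail
threshold 1.01, one automatic retry with doubled iterations) and a
Geyer-type effective sample size. The mixture marginalizes the discrete
membership labels analytically (log-sum-exp across components within
participant); chains are initialized with the component-2 mean at the
upper-quartile logit of the data so they start near the separated mode
when one exists.

Bayes factors use the iterative bridge-sampling estimator with a
moment-matched Gaussian proposal on the unconstrained scale (SDs and
precisions log-transformed; an exponential-prior intercept
log-transformed), iterated to relative tolerance 1e-10. Random
intercepts are integrated as part of the joint, so the estimate is the
marginal likelihood of the full hierarchical model. The Monte Carlo
error estimate treats bridge terms as independent draws — a
simplification of the spectral formula that is adequate at the effective
sample sizes used here and is validated against closed-form conjugate
evidence (normal–normal and beta–binomial) to within 0.05 nats in the
test suite.

Model comparison uses PSIS-LOO: Pareto-smoothed importance sampling with
the Zhang–Stephens generalized-Pareto tail fit, smoothing the largest
`min(0.2 S, 3 sqrt(S))` weights and truncating at the raw maximum. The
reported difference is `elpd_B - elpd_A`, so negative values favor the
first-listed model. For the graded-versus-discrete comparison the graded
model's pointwise log-likelihood is computed **marginally** — the
participant intercept integrated out by 21-point Gauss–Hermite
quadrature — so that both models are scored at the participant level;
conditional pointwise log-likelihoods are also available. With one
observation per participant, conditional LOO would let each random
intercept chase its own observation, which is exactly the situation
PSIS diagnostics flag; the marginal choice avoids it.

## The synthetic-data generator

The generator emulates the study design: 92 participants (default), two
test trials of two 8-s windows at 60 Hz, covariates with the study's
moments (RT mean 563 ms, SD 111.7, truncated to the 200–1800 ms range
the task can measure; verb count mean 54.6, SD 30.2, truncated to the
0–678 items of the vocabulary checklist; total vocabulary at least the
verb count). Default generative parameters are the fitted study values:
graded regime `B0 = 0.04`, `sigma = 0.08`, `phi = 22.7`; discrete
regime components at logits 0.01 and 0.33 with precisions 23.31 and
11.41 and membership probability 0.17. Under these defaults the
simulated spread of per-participant mean proportions (~0.08) brackets
the observed SD.

Micro-structure the source does not specify, chosen once: fixations
follow a two-state Markov dwell process with geometric run lengths
(mean dwell 500 ms at an even share), rescaled so the stationary target
share equals the participant's (per-window beta-drawn) looking
propensity; missingness is inserted as runs of mean 400 ms at a
configurable rate. Windows and trials are conditionally independent
given the participant mean — the study observed a small *negative*
between-trial correlation it did not model, and no autocorrelated
generator is implemented. Looking-while-listening sessions are built
with *planted* reaction times: gaze sits on the distracter until
exactly the planted RT after target-word onset, when a ≥100 ms target
fixation begins, so the extraction rules can be verified exactly;
target-initial and heavily missing trials exercise the filters.

What a green test does **not** establish: the generator produces
stationary, idiosyncrasy-free gaze with independent windows, so
recovery results speak to the statistical machinery, not to whether
real toddler gaze satisfies those assumptions.

## Preprocessing choices

* The "66% missing" window rule is read inclusively
  (`frac_missing >= 0.66` drops the window); participants missing two
  or more of their four windows (dropped or absent) are excluded. The
  cascade is idempotent and fully audited.
* `prop_target` uses valid samples only (target + distracter in the
  denominator), the standard preferential-looking convention; the
  source does not state the denominator.
* The boundary transformation `(y*(n-1) + 0.5)/n` is applied where the
  source applies it — 2000-ms bin proportions, with `n` the number of
  proportions being transformed — and to whole-window proportions only
  if an exact 0/1 occurs (logged when it does).
* "Looking at the screen" for the LWL 50% rule means gaze on either
  image; timestamps are 0-based and intervals half-open `[start, end)`.
  An RT is the onset-relative start of the first ≥100 ms target
  fixation, eligible only if gaze was on the distracter at onset and
  the start falls in [300, 1800] ms.
* Covariates are standardized (mean 0, SD 1, denominator n−1) before
  entering any model; fitted coefficient scales imply this. Verb
  *count* is the exposed default; a proportion-of-verbs variant can be
  standardized the same way (the source is ambiguous about which the
  mixture models used).

## What "well-separated" has to mean

The recovery experiments revealed a substantive constraint worth
recording. With components at proportions 0.50 and 0.70 and the
study-scale precision (`phi ~ 22.7`, component SD ~0.10), a
*single observation per participant* cannot identify the mixture: the
marginal distribution is unimodal, and direct evaluation of the log
posterior shows the one-broad-component explanation (`pi` near 1,
moderate `phi2`) has **more** posterior mass than the true two-component
configuration. Raising the component precisions enough to separate the
humps (e.g. `phi = 100`) is vetoed by the `Gamma(3.5, 0.5)` prior
(about −42 nats at `phi = 100`). The only route to separation that is
compatible with the model's own priors is repeated observations:
with four proportions per participant — the four windows the task
actually yields — per-participant means separate the groups by ~4 SDs,
`pi` is recovered, and PSIS-LOO selects the generating structure
essentially always. The packaged experiments therefore define
"well-separated" as `phi = 22.7` with four observations per
participant, and retain the one-observation design at N = 92 as the
*indeterminacy* check: there the mixture's membership-probability
posterior is diagnostically wide (95% CI width > 0.5), the situation
the study itself reported.

## Numerical details and edge cases

* Beta means are clamped to `(1e-12, 1 - 1e-12)` inside the samplers;
  responses exactly 0 or 1 are rejected at the interface (the
  transformation stage is responsible for removing them).
* `sv_transform(0.5, n)` is exactly 0.5 for every n; endpoints map to
  `0.5/n` and `(n-0.5)/n`.
* Sum coding: window 1 and trial 1 are +0.5, level 2 is −0.5,
  interactions are products; the four-level bin factor uses
  sum-to-zero contrasts scaled to ±0.5. Items are the 16 unique
  (sequence, trial) pairs. The three-way bin model uses random
  intercepts by participant and item (the "full uncorrelated random
  effects" variant reduces to this for the factors retained here).
* The probability-scale summary of a logit-scale parameter applies the
  inverse logit to each draw and then summarizes; quantile summaries
  commute with the transform up to order-statistic interpolation.
* Bridge-sampling proposals add a small ridge (1e-8 of the mean
  diagonal) before the Cholesky factorization; degenerate proposals
  raise an error rather than returning a number.
* Reproducibility: chain c of a fit uses `seed + c - 1`; every packaged
  experiment derives per-replicate seeds from the experiment seed, and
  identical seed + configuration gives bit-identical reports.

## Known limitations

* PSIS-LOO standard errors at n = 92 are large relative to the model
  differences of interest — as in the study, most comparisons at that
  scale are indeterminate; the package reports this honestly rather
  than resolving it.
* Bridge-sampling MC error uses an independence approximation rather
  than a spectral estimate.
* No zero/one-inflated beta variants, at most two mixture components,
  no correlated random effects, no autocorrelated gaze generator, and
  no drift correction or AOI geometry — inputs are already AOI-labelled
  streams.
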