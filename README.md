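# lookmix

Are individual differences in toddlers' comprehension of transitive
sentences **graded** or **discrete**?

In the intermodal preferential looking (IMPL) paradigm, a child hears a
transitive sentence with a novel verb ("the boy is gorping the girl!")
while two videos with opposite participant roles play side by side;
comprehension is indexed by the proportion of 60 Hz gaze samples on the
video that matches the sentence. Two families of theories make opposite
predictions about how that proportion varies across children. If
grammatical knowledge strengthens gradually with input, every child has
their own mean looking propensity — a *mixed model*. If children either
have or have not acquired the abstract construction, the sample splits
into a chance-level group and an above-chance group — a *mixture model*.
`lookmix` implements both models, the preprocessing that produces their
response variable, and the machinery to compare them, together with a
synthetic-data generator so the whole pipeline is testable end to end
without any external data.

## Models

All models use the beta likelihood in its mean–precision
parameterization: shapes are `(μφ, (1−μ)φ)` and the variance is
`μ(1−μ)/(1+φ)`.

**Graded individual differences** (mixed model):

    Prop_i ~ Beta(μ_i, φ)
    μ_i    = inv_logit(B₀ + t_i)
    t_i    ~ Normal(0, σ)

with priors `σ ~ half-Normal(0, 1)` and `φ ~ Gamma(3.5, 0.5)`
(shape–rate). Covariate variants add standardized lexical-processing RT
or verb-vocabulary count to the mean's linear predictor.

**Discrete individual differences** (two-component mixture):

    Prop_i ~ (1 − T_i)·Beta(μ₁, φ₁) + T_i·Beta(μ₂, φ₂)
    T_i    ~ Bernoulli(π)

with component 1 anchored at chance (`Normal(0, 0.05)` on the logit of
μ₁) and component 2 above chance (`Normal(0.4, 0.15)`). Covariate
variants put RT on the group-2 mean logit or verb count on the
membership logit.

**Chance-level tests** are mixed-effects beta regressions with random
intercepts by participant and by item (the 16 unique trial types),
optionally with sum-coded window/trial/bin factors and an
action-salience covariate. Bayes factors against chance compare a null
intercept prior `Normal(0, 0.05)` (95% of mass between proportions 0.48
and 0.52) with alternatives `Normal(0.4, 0.15)` or `Exponential(1)`,
via bridge sampling. Model structure is compared by PSIS-LOO.

All MCMC is a slice-within-Gibbs sampler implemented in C++ (no
external probabilistic-programming dependency); bridge sampling and
PSIS-LOO are implemented in the package and validated in the test suite
against closed-form conjugate evidence and exact leave-one-out refits.

## Worked example

```r
library(lookmix)

# a 92-child study under the graded regime, at the fitted study values
study <- simulate_impl_study(generative_config("graded"), seed = 8)
prep  <- preprocess_study(study$gaze, study$design,
                          covariates = participant_covariates(study$truths))
round(c(mean = mean(prep$participant_means$y),
        sd = sd(prep$participant_means$y)), 3)
#>  mean    sd
#> 0.506 0.095

# fit both structure models to the participant means and compare
fg <- fit_model(graded_spec(),   prep$participant_means, seed = 1)
fd <- fit_model(discrete_spec(), prep$participant_means, seed = 2)
summarize_fit(fg, pars = c("b_intercept", "sigma_participant", "phi"))[, 1:4]
#>           parameter        mean       ci_low    ci_high
#> 1       b_intercept  0.02183972 -0.065005566  0.1076757
#> 2 sigma_participant  0.07970878  0.003029726  0.2098642
#> 3               phi 23.40512450 17.363183290 30.8866070

summarize_fit(fd, pars = c("mu1_logit", "mu2_logit", "pi_logit"))[, c(1, 6:8)]
#>   parameter     p_mean     p_ci_low p_ci_high
#> 1 mu1_logit 0.50220595 0.4856716480 0.5183447
#> 2 mu2_logit 0.58877514 0.5175950813 0.6593971
#> 3  pi_logit 0.05855206 0.0009482854 0.2556201

cmp <- loo_compare(fg, fd, type = "marginal")
round(c(elpd_diff = cmp$elpd_diff, se_diff = cmp$se_diff), 2)
#> elpd_diff   se_diff
#>     -0.31      0.12
```

The graded intercept sits at logit 0.02 (proportion ≈ 0.51) with a
credible interval spanning chance and a small participant-level SD; the
mixture finds a chance group at 0.50 and an above-chance group at 0.59
on the probability scale with a small, uncertain membership
probability; and the LOO difference (negative favors the first-listed
graded model) is modest — the diagnostic situation the recovery
experiments quantify at this one-proportion-per-participant scale. With
four
observations per participant and well-separated groups,
`run_recovery_experiment()` shows LOO selects the generating structure
in ≥ 70% of replicates (in practice near 100%).

## Command line

```sh
Rscript -e 'lookmix::lookmix_cli()' simulate --out sim --seed 1
Rscript -e 'lookmix::lookmix_cli()' preprocess --gaze sim/gaze.csv --out prep
Rscript -e 'lookmix::lookmix_cli()' registry
```
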