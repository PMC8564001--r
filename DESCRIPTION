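Package: lookmix
Title: Graded Versus Discrete Individual Differences in Preferential-Looking Data
Version: 0.1.0
Authors@R:
    person("Canberra", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for asking whether individual differences in toddlers'
    comprehension of transitive sentences, measured as the proportion of
    looks to a target video in the intermodal preferential looking (IMPL)
    paradigm, are graded or discrete. Provides a synthetic-data generator
    for 60 Hz area-of-interest gaze streams under graded (logit-normal
    participant means) and discrete (two-component beta mixture) regimes;
    preprocessing with the standard exclusion cascade, time-bin
    aggregation, zero/one proportion transformation, action-salience
    covariates and looking-while-listening reaction-time extraction;
    Bayesian beta mean-precision mixed and mixture models fitted by
    slice-within-Gibbs MCMC; prior-based Bayes factors via bridge
    sampling; and PSIS-LOO model comparison, plus packaged parameter- and
    model-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
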