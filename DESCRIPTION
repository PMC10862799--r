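Package: npbddm
Title: Nonparametric-Bound Drift-Diffusion Models of Perceptual Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for bounded drift-diffusion analyses of choice-reaction-time
    experiments with time-varying decision bounds. Implements the
    nonparametric-bound drift-diffusion model (npb-DDM), which inverts an
    empirical reaction-time distribution into the time course of the symmetric
    decision bounds by alternating Fokker-Planck propagation of the decision
    variable with an exit-mass matching step, and fits the remaining free
    parameters (signal-to-noise and non-decision time) by maximum likelihood.
    Also provides a forward Monte-Carlo simulator of the three-phase
    random-dot-motion task with provisional Rayleigh deadlines and a points
    economy, a dynamic-programming solver for the earning-rate-optimal stopping
    policy, shape-preserving bound-scaling fits with an exact permutation test
    of bound idiosyncrasy, and the accompanying descriptive statistics
    (phase regressions, time-dependent accuracy, cancellation-aligned
    reaction times).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
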