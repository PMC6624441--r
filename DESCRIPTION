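Package: hlater
Title: Hierarchical Bayesian LATER Models for Reaction-Time Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits the LATER (Linear Approach to Threshold with Ergodic
    Rate) rise-to-threshold model of reaction times in a hierarchical
    Bayesian framework. Each trial's latency arises from a linear evidence
    signal rising at a Gaussian-varying rate ("accretion") toward a
    response threshold ("caution"); person-specific accretion and caution
    parameters receive group-level regressions on person covariates, and
    dummy-coded experimental-condition deviations act on both parameters.
    Includes a Metropolis-within-Gibbs sampler with conjugate updates for
    the accretion block, Gelman-Rubin split-chain convergence diagnostics,
    posterior predictive checks, a generative simulator emulating a
    two-session Go/No-Go study design, and a command-line interface for
    reproducible simulate/fit/check pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
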