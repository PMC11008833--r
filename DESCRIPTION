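Package: tpcfilter
Title: Temporal Predictive Coding Networks for Filtering and System
    Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Temporal predictive coding (tPC) networks: recurrent
    predictive-coding models that filter noisy dynamic observations by
    gradient descent on a variational free energy, with purely local,
    Hebbian learning of the transition and emission weights.  Provides
    the linear and tanh tPC engine (iterative and fully online
    single-step inference, sparse variant), a reference Kalman filter
    together with the analytic tPC equilibrium and a brute-force
    Bayesian-conditioning oracle, simulators for linear-Gaussian
    state-space tracking benchmarks and a noisy nonlinear pendulum, and
    tools for training on movie-like stimuli and estimating
    spatio-temporal receptive fields by white-noise reverse correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
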