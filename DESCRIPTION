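Package: lanssm
Title: Likelihood Approximation Networks for Sequential Sampling Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Amortized Bayesian inference for simulation-only sequential
    sampling models of choice and response time. Simulates a zoo of
    diffusion-type decision models (drift diffusion model and its full
    trial-variability extension, Ornstein-Uhlenbeck, Levy flight, collapsing
    Weibull and linear bounds, N-choice race) by Euler-Maruyama integration,
    builds empirical likelihoods from simulator output (per-choice kernel
    density estimates and binned histograms), trains small neural networks
    (a pointwise multilayer perceptron and a histogram convolutional network)
    as drop-in likelihood evaluators, and performs posterior inference with
    step-out slice sampling, differential-evolution MCMC with reflecting
    boundaries, and annealed adaptive importance sampling with Student-t
    mixture proposals. Ground-truth likelihoods for the drift diffusion
    model are provided through a small-time/large-time series approximation
    of the first-passage-time density, with quadrature extensions for
    trial-to-trial parameter variability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    pracma,
    MASS,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
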