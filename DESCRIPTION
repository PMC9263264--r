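Package: eidyn
Title: Dynamical Mean-Field Analysis of Noise-Driven Excitatory-Inhibitory Random Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing random recurrent rate networks with
    an excitatory and an inhibitory population, reciprocal (intra-population)
    coupling correlations, and additive white noise. Provides the correlated
    block coupling-matrix sampler, an Euler-Maruyama network integrator with
    shared-noise replica pairs, the dynamical mean-field reduction (Gaussian
    pair expectations, stationary means, self-consistent variances and
    long-lag limits, second-order autocorrelation dynamics with energy
    conservation), maximal-Lyapunov-exponent machinery (replica distances,
    linearized cross-correlation field, critical coupling conditions), and
    linear-stability spectral analysis of the network Jacobian.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    pracma,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
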