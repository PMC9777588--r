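Package: chaintherm
Title: Stochastic Thermodynamics and Fluctuation Theorems for Finite Markov Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Work, heat, free energy and dissipated work for finite,
    discrete-time, inhomogeneous Markov chains, together with exact (full
    trajectory enumeration) and Monte Carlo verification of Jarzynski's
    equality and Crooks' fluctuation theorem, time reversal and microscopic
    reversibility diagnostics, and an application layer for bounded-rational
    (maximum-entropy) decision-making: Boltzmann policies, Metropolis
    learners with a prescribed stationary distribution, surprise accounting
    and hysteresis under reversed environment schedules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
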