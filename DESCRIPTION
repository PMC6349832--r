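Package: eidesign
Title: Adaptive Optimal Stimulus Design for Excitatory-Inhibitory Rate Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop adaptive stimulus design for estimating the parameters of a
    two-unit excitatory-inhibitory firing-rate network from Poisson spike trains.
    Simulates the network and its forward sensitivity equations with a fixed-step
    integrator, represents time-varying stimuli as bounded Fourier series, designs
    stimuli by maximizing per-parameter A-optimal Fisher-information utilities with
    analytic gradients, estimates the time constants and connection weights by
    multistart bounded maximum likelihood, and provides post-hoc analyses of recovery
    accuracy, likelihood efficiency, local-optima probability, and parameter
    confounding.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    optparse,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
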