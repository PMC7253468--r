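Package: lvcomm
Title: Stability and Resilience of Random Lotka-Volterra Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how mutualistic interactions affect the
    stability of model ecological communities. Generates random
    Lotka-Volterra interaction matrices with a controlled proportion of
    mutualistic (+/+) pairs over an exploitative, competitive or random
    background, solves for interior equilibria and tests their
    feasibility, analyses the density-weighted community matrix S = DA
    spectrally (leading eigenvalue, bulk/outlier decomposition, trace
    identities), integrates the nonlinear dynamics under pulse
    perturbations, and orchestrates seeded parameter sweeps and
    perturbation-recovery experiments with tidy tabular outputs and
    ggplot2 graphics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
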