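Package: huddlesoc
Title: Thermoregulatory Huddling Simulators and Self-Organised Criticality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators of rodent thermoregulatory huddling and the evolutionary
    dynamics they induce. Provides a thermodynamic Monte Carlo (Ising-analog)
    model of group merge/split dynamics, a Vicsek-style agent-based model with
    thermal sensing and homeothermotaxis turning, a weakest-substitution
    evolutionary procedure over either simulator, and self-organised-criticality
    analysis of the resulting traces (histograms of the second-weakest metabolic
    rate, log-log power-law regression, avalanche segmentation, and
    exponent-versus-temperature sweeps). All experiments are reproducible from a
    config and a seed, with tidy tabular outputs and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    igraph,
    generics,
    withr,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
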