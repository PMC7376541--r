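Package: fdnotch
Title: Fractional-Order Delta-Notch Models of Boundary Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for fractional-order Delta-Notch
    lateral-inhibition models of boundary-cell patterning in the Drosophila
    large intestine. Provides a Grunwald-Letnikov fractional integrator with
    short-memory truncation and a forward-Euler reference path, closed-form and
    Cardano-based equilibrium computation with Newton refinement, local
    stability analysis (Routh-Hurwitz and the fractional argument condition),
    Morris elementary-effects sensitivity screening, and multi-cell lattice
    phenotype experiments with heatmap output. Results are returned as tibbles
    with ggplot2 autoplot() and broom-style tidy()/glance() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
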