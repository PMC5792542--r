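Package: ipnets
Title: Interacting Phenotypes on Weighted Social Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation and closed-form quantitative-genetic
    predictions for socially plastic traits on weighted social networks.
    Generates spatially structured interaction networks with tunable density
    and phenotype-based assortment (homophily or heterophily), computes
    individual phenotypes under an interaction-coefficient (psi) model of
    indirect genetic effects without phenotypic feedback, and summarises
    per-group phenotypic variance, direct-indirect correlations, total
    breeding values, and the covariance-based response to a linear selection
    gradient. Includes seeded replicate sweeps over interaction range and
    homophily strength, tidy long-format outputs, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
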