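Package: mortnet
Title: Metapopulation Modelling of Regional Mortality Correlation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to model monthly all-cause mortality across a set of
    regions as the sum of a biphasic (U-shaped) temperature effect, a
    region-specific baseline, and an infective component driven by a
    monthly-restarting SIR epidemic on a traveller-flux network. Includes
    gravity-model fits of commuter and episodic flux, a stochastic
    maximum-likelihood trainer for the full flux-temperature model,
    correlation-network reconstruction and degree-anomaly scoring, and a
    synthetic-data generator with known ground truth for parameter-recovery
    testing.
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
    geosphere,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
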