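Package: phasetip
Title: Physiological Performance Surfaces and Trophic Tipping Points
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates how multiple nonlinear environmental drivers
    (temperature and seawater pCO2) reshape the balance between primary
    production and consumption in a two-species producer-consumer system.
    Provides parametric biphasic driver-performance curve families (thermal
    performance curves, saturating and threshold pCO2 responses, hormetic
    dose responses), multiplicative two-driver performance surfaces on a
    temperature-by-pCO2 grid, net production-consumption surfaces, realized
    secondary production, phase-state classification with zero-isocline
    (tipping boundary) extraction, instability (steepness) mapping,
    perturbation-arrow classification, named preset scenarios, synthetic
    observation generation with curve fitting for parameter recovery, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
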