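Package: thermindex
Title: Personal Thermal Stress Assessment from Weather Forecasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes personalised heat- and cold-stress assessments from
    standard 3-hourly weather-forecast fields and a personal context
    (activity, clothing, body characteristics, heat acclimatisation,
    indoor/outdoor situation). Implements the Liljegren outdoor wet bulb
    globe temperature (WBGT) model, the ISO 7933 Predicted Heat Strain
    simulation, the ISO 11079 required clothing insulation (IREQ) model,
    the ISO 7730 PMV/PPD comfort model and the JAG/TI windchill index, and
    collapses them into a single personal thermal stress index on a -4
    (extreme cold) to +4 (extreme heat) scale with decision-tree advice
    codes and 24 h index forecasts.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
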