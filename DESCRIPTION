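Package: ozonehia
Title: Ozone Health Impact Projection Under Climate and Population Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reproducible pipeline for projecting ozone-related
    acute excess mortality under climate/emission and population scenarios:
    statistical downscaling (bias-correction spatial disaggregation, BCSD) of
    coarse chemistry-climate-model MDA8 ozone fields to a fine grid using
    monthly quantile bias maps, city-level exposure construction from
    area-weighted grid cells, attributable-fraction health impact assessment
    stratified by cause, age group and season, Monte Carlo empirical
    confidence intervals over concentration-response-function draws and
    climate-model ensemble members, and incremental decomposition of burden
    changes into climate, population-size, aging and mortality-rate drivers.
    Includes a synthetic-data generator with known ground truth (injected
    model bias, injected future trends, demographic shifts) so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    lubridate,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    ncdf4,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
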