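Package: grassagb
Title: Grassland Aboveground Biomass Dynamics from Light-Use-Efficiency
    Productivity Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating grassland aboveground biomass (AGB) from
    gridded NDVI and meteorological time series with a light-use-efficiency
    (CASA-type) net primary productivity model, converting productivity to
    biomass with per-type root:shoot allocation, estimating grazing intensity
    from the production/standing-crop balance, and characterising AGB
    dynamics with per-pixel Theil-Sen slopes, Mann-Kendall tests, coefficient
    of variation stability levels, Pearson correlation categories and
    random-forest driver importance. Includes a synthetic-scenario generator
    with stored ground truth so every stage can be validated end-to-end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vctrs,
    yaml
Suggests:
    optparse,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
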