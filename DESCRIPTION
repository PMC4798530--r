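Package: carbonbook
Title: Carbon Bookkeeping Model for Net Emissions from Land-Use Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A Tier 3 carbon bookkeeping model for estimating net CO2
    emissions from land-use change on a pixel grid with decadal land-cover
    observations. Tracks sub-pixel cohorts year by year through clearing,
    degradation, abandonment and regrowth, using logistic aboveground-carbon
    regeneration curves, linear soil-organic-carbon decomposition and
    recovery, and root carbon via root:shoot ratios. Includes a Tier 1
    committed-emissions comparator, a sensitivity-scenario engine
    (biomass percentile, pasture share, soil-carbon loss fraction,
    degradation severity, soil erosion, mature-forest sink), reporting by
    administrative unit with per-capita and per-GDP indicators, and a
    synthetic landscape generator so the full pipeline is testable without
    proprietary GIS inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
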