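Package: heatwhl
Title: Projecting Heat-Stress Labor Losses from Gridded Climate Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for projecting occupational heat-stress labor losses
    under climate-change scenarios. Computes gridded indoor and outdoor wet
    bulb globe temperature (WBGT) from daily meteorology, disaggregates daily
    WBGT to work-hour values, calibrates cumulative-distribution
    exposure-response functions linking WBGT to the fraction of work time
    lost at three work intensities (200, 300 and 400 W), builds the gridded
    exposed working population from total population, urbanization and sector
    employment shares with an air-conditioning adjustment, and combines these
    into work-hours-lost (WHL) projections with provincial and period
    aggregation, factor-separation driver attribution, and avoided-loss and
    economic-benefit calculations for a 1.5 degree warming target. Includes a
    synthetic-data generator emulating scenario-dependent gridded climate,
    population trajectories and work/rest tables so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
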