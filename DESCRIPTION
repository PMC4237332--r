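Package: psrbdash
Title: Pressure-State-Response-Benefit Biodiversity Indicator Pipeline
Version: 0.1.0
Authors@R: person("PSRB", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Computes the four indicator families of a
    Pressure-State-Response-Benefit (PSRB) biodiversity dashboard,
    disaggregated to arbitrary regional or national analysis units:
    gross forest cover loss rate (pressure), the Red List Index of
    species survival with genuine-change back-casting (state),
    protected-area coverage of key biodiversity areas with a
    bootstrap time series over imputed establishment dates (response),
    and a quality-weighted freshwater provision index routed over D8
    drainage directions (benefit), plus a questionnaire-based
    monitoring-capacity score. Ships a seeded synthetic-data generator
    that emulates the statistical structure of the global inputs
    (gridded forest cover and loss, species assessment tables,
    protected-area and key-biodiversity-area polygons, runoff,
    population and drainage grids, survey responses) with known ground
    truth, so every stage of the pipeline is testable end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
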