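Package: snowphen
Title: Breeding-Season Phenology of Alpine Birds from Citizen-Science Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the start, end, and duration of the breeding season of
    alpine birds from citizen-science breeding-evidence records, and relates
    them to temperature, precipitation, and snow conditions. Phenology curves
    are fitted per year with hierarchical binomial generalized additive models
    built on cyclic cubic regression splines (a global day-of-year smoother
    shared across biogeographic regions plus shrunken per-region deviation
    smoothers); season start and end are extracted as threshold crossings of
    the expected proportion of likely-breeding observations, with a
    threshold-sensitivity analysis. Snowmelt timing and duration are derived
    from daily snow-cover fractions. A sliding-window scan identifies the
    climate windows whose mean temperature or number of precipitation days
    correlate most strongly with the phenology metrics, filtered by the
    standard error of the Pearson correlation. Linear mixed-effect models with
    year and region random intercepts quantify the climate effects in
    standardized and unstandardized form, and linear trend models track the
    change of breeding-season temperature across years. A seeded synthetic-data
    generator with planted effects provides a parameter-recovery test surface
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    lme4,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
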