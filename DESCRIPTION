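Package: wssphen
Title: Growing Degree-Day Phenology Models for Wheat Stem Sawfly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for modelling the spring emergence of adult wheat stem
    sawfly (Cephus cinctus) from sweep-net monitoring data and daily weather
    records. Implements single-sine growing degree-day (GDD) accumulation
    with an upper-threshold horizontal cutoff, a coefficient-isolation
    Poisson random-effects phenology model that locates the start, peak,
    and end of the flight on the GDD axis, a cumulative-proportion probit
    model that answers emergence-quantile queries, and a mixed model of
    site-year population magnitude with backward selection over
    environmental covariates. A seeded simulator generates multi-site,
    multi-year weather and capture datasets with the statistical structure
    these models assume, so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
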