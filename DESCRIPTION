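Package: lursurv
Title: Land Use Regression Exposure Models and Cohort Mortality Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds land use regression (LUR) models for nitrogen dioxide
    from passive-sampler monitoring campaigns, validates them
    (leave-one-out cross-validation, variance inflation factors, Cook's
    distance, Moran's I of residuals), calibrates measurements between
    sampler types, transports models across measurement periods taken
    years apart, assigns modelled exposure to cohort addresses, and
    relates exposure to natural mortality through a self-contained Cox
    proportional-hazards fitter. A synthetic-city generator with known
    ground truth (geometry, latent pollution surface, co-located sampler
    pairs, cohort survival times) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    ape,
    car
Config/testthat/edition: 3
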