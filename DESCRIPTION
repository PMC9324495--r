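Package: terpflux
Title: Hourly Terpene Emission Modelling for Temperate Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates hourly, fine-resolution (30 m) emission rates of
    human-beneficial monoterpenes and sesquiterpenes from forest landscapes
    using a modified MEGAN v2.1 canopy emission model. Includes conversion of
    station weather to model drivers (PPFD, rolling temperature and light
    history, topographic solar-incidence correction on a DEM), NDVI-based
    leaf-area phenology (Hampel outlier repair and double-logistic smoothing),
    leaf-age dynamics, per-pixel emission simulation over plant-functional-type
    mosaics, seeded synthetic-data generation for testing, and the temporal and
    spatial aggregation and rank-based group-comparison statistics used to
    characterise diurnal, seasonal, aspect and forest-type emission patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
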