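Package: wrastichi
Title: Multi-Criteria Assessment of Lake Ecosystem Degradation from Watershed Characteristics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements the WRASTIC-HI multi-criteria index for assessing the
    degradation state of lake ecosystems from the characteristics of the
    watershed that feeds them. Scores seven pressure indicators (wastewater,
    recreation, agriculture, watershed size, transportation, industry,
    vegetative cover) and three hazard factors (slope, aspect, soil
    permeability) on integer rubrics, aggregates them by a weighted sum,
    assigns one of three hazard types, and classifies each lake as natural,
    semi-degraded or degraded. Provides a tabular engine verifiable against a
    bundled 30-lake reference dataset, a lightweight geospatial engine
    (raster grids, Horn slope and aspect, zonal statistics, Jenks natural
    breaks, vector predicates) that derives the scores from raster and
    vector layers, and a deterministic synthetic-scene generator with
    construction-time ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
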