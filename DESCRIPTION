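Package: nestherm
Title: Energy-Balance Simulation of Sea Turtle Nest Incubation Temperatures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Transient three-dimensional heat-conduction simulation of a sea
    turtle nest: beach sand, repacked egg-chamber sand and a gravity-packed
    clutch of spherical eggs, with per-egg metabolic heat sources driven by a
    temperature-dependent embryonic development model. Effective thermal
    properties of the sands are derived from field bulk density and moisture
    by Mori-Tanaka homogenisation and a rule of mixtures. Per-egg temperature
    histories feed predictions of incubation duration, hatchling sex (Hill
    reaction norm over the thermosensitive period) and hatching success, and
    a synthetic boundary-temperature generator makes the whole pipeline
    testable without field logger data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    caret,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
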