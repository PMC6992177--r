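Package: marshwvi
Title: Wetland Vulnerability Indices over Hydrologically Delineated Marsh Units
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Delineates coastal wetland complexes into hydrologically defined
    marsh units from an elevation grid (D8 steepest-descent flow routing,
    drainage-basin labelling, iterative minimum-area merging), summarizes
    physical and biophysical indicator layers over the units (zonal means,
    shoreline-change averaging, unvegetated-to-vegetated ratio), ranks each
    indicator into equal-occupancy vulnerability categories and aggregates
    them into a wetland vulnerability index (WVI) with chronic-only and
    episodic-only variants. Includes multivariate structure analysis
    (cross-correlation, principal components with three retention rules,
    expectation-maximization Gaussian-mixture clustering with BIC model
    selection, cluster departure profiles), hotspot zoning by buffer,
    unit-count and area rules, transect profiles, and seeded synthetic-data
    generators (multi-basin elevation surfaces, tessellated unit geometries,
    Gaussian-copula indicator tables, mixture-structured unit populations)
    for fully reproducible testing of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
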