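Package: ballastgwr
Title: Mineral Ballast Partitioning of Surface Particle Export with
    Geographically Weighted Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing where mineral ballast matters for the surface
    export of particulate organic carbon (POC). Derives export fluxes from
    thorium-234/uranium-238 disequilibria via the one-dimensional steady-state
    model, decomposes POC export into calcite-, opal- and lithogenic-associated
    portions with a global multiple linear regression and a geographically
    weighted regression (GWR) built on an adaptive Gaussian kernel with
    AICc bandwidth selection, tests the spatial variability of the carrying
    coefficients, compares models by ANOVA and residual Moran's I correlograms,
    and maps the percent of export that is ballast-associated. Includes a
    synthetic station-table generator with known spatially varying coefficient
    fields for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    jsonlite,
    withr
Config/testthat/edition: 3
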