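Package: greyplus
Title: Land-Use Change Accounting, Ecosystem-Service Valuation and Grey
    Multi-Objective Scenario Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for coupled land-use/land-cover (LULC) change analysis in
    data-scarce basins: per-class area accounting with single land-use dynamic
    degrees and Markov projection; equivalent-factor ecosystem-service
    valuation (ESV) with a dynamic standard equivalent and biomass (NPP/FVC)
    and social-development (GDP/Engel) corrections; grey multi-objective
    linear programming (GMOP) of land-use structure with GM(1,1) grey
    forecasting and interval ("grey") coefficient sensitivity; a simplified
    patch-generating cellular-automaton spatial allocator with
    expansion-sample suitability learning (LEAS); land-change validation
    metrics (kappa, overall accuracy, figure of merit); and a synthetic-data
    generator with known transition structure so the whole pipeline is
    testable without proprietary rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    jsonlite,
    ranger,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
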