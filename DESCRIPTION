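Package: thermorange
Title: Mechanistic Invasion-Risk Modelling for Endothermic Birds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully testable pipeline for mechanistic
    (biophysical) invasion-risk forecasting in endothermic birds. Monthly
    climate normals are downscaled to hourly microclimates at animal height,
    a steady-state heat-balance model with a physiological-then-behavioural
    thermoregulatory cascade returns the metabolic rate required to hold
    core temperature, and hourly energetics are aggregated into per-pixel
    survival, breeding and invasion-risk classifications. An iterative
    Latin-Hypercube sensitivity workflow trims trait ranges against
    occurrence data, a per-pixel intraspecific ensemble relaxes single-value
    trait assumptions, and niche-dynamics (expansion, stability, unfilling,
    equivalency and similarity randomization tests) and forecast-evaluation
    statistics (TSS, partial ROC, MOP extrapolation masks, potential niche
    truncation) close the loop. Seeded synthetic landscape, climate, species
    and occurrence generators with analytically known thermal limits make
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    geosphere,
    lhs,
    randomForest,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
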