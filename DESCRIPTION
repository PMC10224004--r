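Package: partperm
Title: Dissolution Thermodynamics, Phase Distribution, Cyclodextrin
    Complexation and Membrane Permeability Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physicochemical transport-property analysis for small-molecule
    drugs: van't Hoff dissolution thermodynamics from temperature-dependent
    solubility, apparent distribution coefficients and the delta-logD
    hydrogen-bonding parameter in two-phase organic/aqueous systems,
    drug-cyclodextrin association constants by the phase-distribution
    method, and apparent permeability from Franz diffusion cell time
    courses with sampling-replacement correction. Includes seeded
    synthetic-experiment generators for all three experiment types so
    every estimator can be validated by simulation at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
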