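Package: debsim
Title: Standard Dynamic Energy Budget Simulation under Constant and Seasonal Food
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the standard Dynamic Energy Budget (DEB) model for an
    ectotherm under constant and seasonally oscillating food availability.
    Provides the model's energy fluxes, life-stage switching, and observable
    transforms; numerical integration with deSolve; an interspecific parameter
    sweep over assimilation, conductance, and allocation; per-run summaries
    (time to puberty, steady-state and long-run biomass, cumulative
    reproduction energy); analytic validation against the reserve-density and
    ultimate-length closed forms; and a curation pipeline for species-parameter
    tables (lifespan/completeness filtering, interquartile-range outlier
    fences, joint discretization, frequency pruning) together with a synthetic
    table generator for testing that pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
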