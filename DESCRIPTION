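Package: limnoch4
Title: Surface Mixed Layer Methane Mass Balance for Stratified Lakes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying oxic methane production in the surface
    mixed layer (SML) of stratified lakes from a whole-basin mass balance.
    Provides lake geometry derivation from hypsometry, floating-chamber flux
    and k600 wind-speed gas exchange models, heat-budget vertical
    diffusivity with Fick's-law thermocline fluxes, steady-state mass
    balance solvers with Monte Carlo uncertainty propagation, an empirical
    exponential scaling of the oxic methane contribution against littoral
    sediment area per SML volume with global upscaling, and a synthetic
    field-campaign generator with known ground truth for end-to-end
    validation.
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
    withr
Config/testthat/edition: 3
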