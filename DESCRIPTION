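Package: cofusion
Title: Growth Kinetics and Dynamic Metabolic Modeling of Fusing Clostridial Cocultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a syntrophic Clostridium acetobutylicum / Clostridium
    ljungdahlii coculture in which cells fuse membranes and exchange
    proteomes. Provides monotone (PCHIP-family) interpolation of growth
    curves and time-dependent specific growth rates, a hybrid-state cell
    fusion ODE system with a single second-order fusion rate constant
    fitted by weighted least squares, a lightweight constraint-based
    metabolic modeling layer (FBA, FVA, blocked-reaction analysis, biomass
    rescaling, SBML/JSON import), hybrid genome-scale model construction
    with energy-generating-cycle removal and flux-variability
    gain-of-function reports, and a dynamic multispecies metabolic
    simulator (DMMM) coupling twelve subpopulation models to the fusion
    growth model with hybrid-state glucose uptake efficiencies,
    H2/CO2 cross-feeding, and maximum-theoretical-titer tracking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
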