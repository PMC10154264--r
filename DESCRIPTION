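Package: ccmflux
Title: Temperature-Resolved Inorganic Carbon Flux Modeling of the Diatom
    Carbon Concentrating Mechanism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for membrane inlet mass spectrometry (MIMS)
    studies of the biophysical carbon concentrating mechanism (CCM) in marine
    diatoms across temperature. Provides seawater carbonate-system speciation
    and uncatalyzed CO2/HCO3- interconversion kinetics, extraction of
    photosynthetic and inorganic-carbon uptake rates from chamber gas traces,
    a forward model and estimator for the 18O/13C isotope-exchange carbonic
    anhydrase assay, Arcus-equation temperature interpolation of RuBisCO
    carboxylation kinetics, a four-compartment (surface, cytosol, chloroplast
    stroma, pyrenoid) steady-state "chloroplast pump" flux model with
    calibration to observed rates, membrane-transport thermodynamics and
    ATP-cost accounting, and synthetic-data generators with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
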