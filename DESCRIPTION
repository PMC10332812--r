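Package: isoflux
Title: Metabolic Flux Analysis of Proliferating Cell Cultures from 13C Labeling Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying metabolic fluxes in proliferating primary
    cell cultures. Estimates growth rates and extracellular metabolite fluxes
    from culture time courses under an exponential-growth mass balance with
    evaporation and spontaneous-degradation corrections; corrects measured
    mass isotopomer distributions for natural isotope abundance; represents
    compartmented carbon-transition networks and decomposes them into
    elementary metabolite units (EMUs); simulates isotope labeling at
    isotopic steady state and during the nonstationary approach to it; fits
    fluxes to labeling and extracellular-flux measurements by multi-start
    weighted least squares with chi-square goodness-of-fit testing and
    confidence intervals; and implements quality-control processing for
    LC-MS metabolomics (pooled-QC drift correction, feature filtering,
    imputation, and probabilistic quotient normalization). Includes a
    synthetic-data generator that emulates the statistical structure of the
    culture, labeling, and metabolomics measurements for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    deSolve,
    minpack.lm,
    pracma,
    randomForest,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
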