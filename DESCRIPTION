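Package: chloroTEA
Title: Techno-Economic Simulation of Chlorophyll Production from a
    Microalgal Consortium
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Transparent, testable model of large-scale microalgal
    cultivation and chlorophyll extraction: spectrophotometric assay
    calibrations (optical density to dry cell weight; two-wavelength
    chlorophyll a/b quantification), logistic growth dynamics per trophic
    mode (phototrophic, heterotrophic, mixotrophic), a synthetic
    laboratory-experiment generator for calibration and fitting studies, a
    steady-state mass-balance flowsheet of a 1-ha photobioreactor farm with
    chitosan flocculation, filter-press dewatering, methanol extraction and
    evaporation with solvent recycle, and a factored annual operating-cost
    model (raw materials, labor, facility-dependent costs, utilities) with
    unit production costs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
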