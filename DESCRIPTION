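Package: cdisoflux
Title: Cadmium Isotope Mass Balance and Rayleigh Fractionation in Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying cadmium uptake and root-to-shoot
    translocation in hydroponically grown plants from per-organ dry biomass,
    Cd concentrations and natural-abundance Cd stable isotope compositions
    (delta 114/110 Cd). Implements exponential-law double-spike inversion and
    isotope-dilution data reduction for MC-ICP-MS ratio measurements, per-plant
    element and isotope mass balance (delta/Delta arithmetic, partition
    fractions, translocation factors, inverse-variance treatment averaging),
    closed-system Rayleigh fractionation estimators for uptake and
    sequestration/mobilisation fractionation factors including a forced-origin
    least-squares fit, nonparametric group comparison with an exact permutation
    option, and a synthetic hydroponic-experiment generator for end-to-end
    pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
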