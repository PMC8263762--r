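Package: lakegas
Title: Dissolved-Gas Biogeochemistry of Stratified Soda Lakes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computations for dissolved-gas biogeochemistry in stratified
    (meromictic) alkaline lakes: headspace-to-dissolved gas partitioning by
    Henry's law, carbonate-system speciation and the del13C-CO2 isotope mass
    balance from del13C-TDIC, thin-boundary-layer water-air CO2 and CH4
    diffusive fluxes with Schmidt-number scaling, a registry of wind-based
    k600 transfer-velocity models, chemical enhancement of CO2 invasion at
    high pH, depth-profile diagnostics (chemocline and oxycline location,
    oxygen saturation, gas depletion-depth extrapolation, chlorophyll-a from
    absorbance), and a van Krevelen / Spearman rank-correlation screen
    relating molecular-formula abundances of dissolved organic matter to the
    CH4 depth profile. Includes a synthetic stratified-lake data generator
    with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
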