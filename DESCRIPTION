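Package: alfaghg
Title: Greenhouse-Gas Accounting for Alfalfa Water-Nitrogen Field Campaigns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chamber-to-climate-metric accounting chain for static-chamber
    greenhouse-gas campaigns in irrigated alfalfa systems. Converts gas
    chromatograph peak areas to concentrations, estimates areal N2O, CO2 and
    CH4 fluxes from closed-chamber concentration time series by linear
    regression, integrates fluxes to per-harvest and seasonal cumulative
    emissions by the trapezoid rule, and derives resource-efficiency and
    climate metrics: water-filled pore space, irrigation water productivity,
    partial factor productivity of nitrogen, the fertiliser-induced N2O
    emission factor, life-cycle global warming potential (soil non-CO2 fluxes
    plus input-chain emissions) and greenhouse-gas emission intensity. A
    synthetic campaign generator emulates a 3-irrigation x 4-nitrogen
    factorial with event-pulsed fluxes so the full pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
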