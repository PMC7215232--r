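Package: precoolr
Title: Zonal Simulation of Forced-Air Precooling of Packaged Strawberries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale zonal (compartment) simulator for the forced-air
    precooling of packaged strawberries. Replaces conjugate CFD with a
    flow-network plus well-mixed-zone surrogate: radial-conduction fruit
    spheres exchange heat with chained air zones whose flows follow either
    prescribed vent-split tables or an orifice-resistance network. Includes
    the full fruit transpiration (moisture-loss) submodel built on
    Sherwood-Reynolds-Schmidt mass-transfer correlations, a library of four
    package/tray vent designs, cooling metrics (7/8th cooling time, cooling
    heterogeneity, cumulative moisture loss), and a synthetic thermocouple
    validation harness with parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
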