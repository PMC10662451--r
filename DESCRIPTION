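Package: fluxgap
Title: Reconciling Earth-Observation and National-Inventory Forest Carbon Fluxes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing forest-related greenhouse-gas flux estimates
    derived from gridded earth-observation products with estimates reported in
    national greenhouse-gas inventories. Implements an IPCC gain-loss flux
    engine over gridded landscape layers, a ladder of managed-land and
    forest-category adjustments that align earth-observation accounting with
    inventory conventions, temporal harmonization of fluxes reported over
    different periods, and the comparison statistics used in inventory
    reconciliation (modal removal factors, percentage differences,
    classification cross-tabulations, mask overlaps, area tables and
    aboveground-carbon summaries). Includes a seeded synthetic-landscape
    generator emulating a tropical-country mosaic of primary forest,
    secondary regrowth and plantations with stochastic forest loss.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
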