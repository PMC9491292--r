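Package: hgdep
Title: Resistance-Based Modelling of Atmospheric Mercury Uptake by Vegetation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating the vegetation sink of atmospheric elemental
    mercury (Hg0). Implements a big-leaf, resistance-in-series dry-deposition
    velocity model with species scaling through the effective Henry's law
    constant (H*) and biological reactivity (f0), land-surface handling
    (fractional land-use composition, leaf-area-index cycles, site land-type
    overrides, savannization scenarios), a pipeline deriving annual dry
    deposition velocities from litterfall, throughfall and wet-deposition
    fluxes with STP-to-local concentration correction, a three-box
    atmospheric Hg0/Hg2+ mass-balance model for tuning the aqueous Hg2+
    reduction coefficient, regional deposition budget bookkeeping, and
    synthetic generators for meteorology, land surface and site measurement
    databases so the full analysis runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
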