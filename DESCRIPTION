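Package: glacialCH4
Title: Methane Budgets of Glacial Runoff: Headspace Concentrations, Oxidation
    Rates, Gas Transfer and Upscaling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Calculation chain for dissolved methane budgets in
    land-terminating glacial runoff. Recovers dissolved CH4 concentrations
    from helium-headspace gas chromatography measurements by Henry's-law mass
    balance, estimates net microbial methane oxidation or production rates
    from sediment-water bottle incubations (per volume, per sediment area and
    per sediment mass), parameterizes gas transfer velocities (k600) from
    river energy dissipation and lake wind speed with Schmidt-number scaling
    to CH4, computes diffusive air-water fluxes from excess concentration,
    attenuates a methane load over a river reach via residence time and
    zero-order oxidation, and upscales per-glacier annual fluxes to global
    glacier coverage. Includes a synthetic-data generator with known ground
    truth for offline validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
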