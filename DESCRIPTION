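Package: methylolation
Title: Kinetics and In-Line Spectroscopic Monitoring of Lignin Methylolation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying the hydroxymethylation (methylolation) of
    lignosulphonates with formaldehyde. Implements a second-order kinetic
    model with a non-reactive phenolic fraction and an optional secondary
    formaldehyde-consuming reaction, with closed-form and numerical
    trajectory simulation and deterministic multi-start least-squares
    parameter estimation from off-line assay series. Provides UV-based
    quantification of lignosulphonate content (Beer-Lambert at 232.5 nm)
    and of phenolic hydroxyl groups by differential ionization
    spectroscopy, a principal-component-analysis workflow for calibrating
    in-line visible spectra against the modelled phenolic hydroxyl decay,
    and a synthetic spectro-kinetic data generator so every stage can be
    exercised end to end without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
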