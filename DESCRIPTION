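Package: iseflux
Title: Analysis and Simulation of Self-Referencing Ion-Selective
    Electrode Flux Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for non-invasive ion-flux measurements with
    self-referencing (scanning) ion-selective microelectrodes. Reads and
    writes plain-text electrode recordings, splits them into position
    loops, extracts drift-corrected voltage differences between the two
    measurement positions by the paired-regression procedure, fits
    Nernstian calibration curves, and converts voltage differences into
    ion fluxes by either the chemical-potential or the Fick
    diffusion-gradient formalism, with corrections for cylindrical or
    spherical tissue geometry and for pH buffering of proton fluxes. A
    physics-based simulator generates synthetic recordings over
    steady-state diffusion fields with known ground-truth flux, so every
    analysis stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
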