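Package: darktrap
Title: Dark-State Trapping Kinetics and Photodetachment Energetics of
    Anionic Chromophores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis toolkit for gas-phase photodetachment and excited-state
    trapping studies of chromophore anions such as the meta isomer of the
    GFP chromophore (meta-HBDI).  Implements photodetachment channel
    energetics over a calculated/measured electronic level diagram,
    RRKM/quasi-equilibrium statistical lifetimes built on exact
    Beyer-Swinehart harmonic state counting, a sequential three-state
    kinetic model with Gaussian instrument-response convolution for joint
    fitting of prompt and delayed pump-probe action transients, photon-order
    power-law analysis of laser fluence series, forward simulation of
    two-dimensional photoelectron spectra, and seeded synthetic-data
    generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
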