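Package: nanowinch
Title: Mechanics and Readout Analysis for DNA-Origami Piston Actuators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a DNA-origami piston-cylinder actuator whose single- or
    double-stranded DNA connectors act as antagonistic entropic springs against
    a linear protein spring. Provides worm-like-chain force-extension,
    stiffness and elastic-energy functions, equilibrium force-balance solving
    with a calibrated one-coordinate geometry, Boltzmann-ensemble piston
    position distributions by quadrature and seeded Metropolis sampling,
    rigid-rod extension prediction for hybridized connectors, a hairpin
    rupture-force benchmark, and the accompanying readout computations:
    TEM inter-domain distance summaries, flow-cytometry bead-calibration
    regression with per-cell counts, time-resolved FRET ratio reduction, and
    two-state idealization of single-channel current traces. Seeded synthetic
    generators emulate every consumed input so the full pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
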