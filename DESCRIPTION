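Package: poolgrowth
Title: Size-Dependent Growth of Intracellular Structures from a Limiting
    Subunit Pool
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stochastic and deterministic models for the growth of
    intracellular structures and organelles that assemble from a shared,
    possibly limiting, pool of molecular subunits. Assembly and
    disassembly rates carry power-law size feedback with exponents alpha
    and beta; the sign of alpha + beta separates robust negative-feedback
    size control, the degenerate limiting-pool line, and bistable
    autocatalytic growth. Provides exact stationary size distributions of
    the chemical master equation via detailed balance, an exact Gillespie
    simulator (with optional subunit production and linear cell growth
    channels), ODE fixed-point and linear stability analysis,
    steady-state size-scaling formulas, organelle applications (flagellar
    length control, centrosome assembly, a liquid-liquid phase separation
    reduction, and nuclear size control coupled to a microtubule aster),
    and ensemble diagnostics such as residence times, dynamic-state
    classification, coexistence phase maps and polarity selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
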