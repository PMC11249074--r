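Package: fibersim
Title: Mechanohydraulic Simulation of Cotton Fiber Elongation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the elongation of single cotton fiber cells with a
    two-variable mechanohydraulic model coupling irreversible (Lockhart)
    cell-wall expansion to water and solute exchange across the plasma
    membrane and through plasmodesmata. Provides the piecewise turgor
    closure that eliminates fiber pressure algebraically, an adaptive ODE
    simulator with time-varying parameter schedules (extensibility decay,
    plasmodesmata closure windows, solute pulses), one-factor-at-a-time
    sensitivity analysis and maximal-change sweeps over biological
    parameter ranges, classification of pressure trajectories as monotonic
    or peaked, and a command-line interface reproducing the standard
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
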