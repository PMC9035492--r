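Package: tregsim
Title: Simulation of Regulatory T Cell Adoptive Transfer in Transplant Rejection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Two-compartment ordinary differential equation model of the
    alloimmune response to a murine heart transplant, with an exponentially
    decaying multi-dose input describing adoptive transfer of regulatory
    T cells (Tregs). Provides a stiff-capable simulator with dose-discontinuity
    handling, rejection-time readouts, dosing-strategy sweep experiments
    (accumulation site, dose magnitude, timing, frequency, graft fraction),
    per-channel attribution of graft destruction, a from-scratch NSGA-II
    multi-objective evolutionary calibrator, and a synthetic-data generator
    for ground-truth parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
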