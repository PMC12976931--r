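Package: inducible
Title: Thermodynamic Models and Dynamics of Effector-Inducible Gene Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical-mechanical modelling of gene regulatory motifs whose
    transcription factors are controlled by small-molecule effectors.
    Implements Monod-Wyman-Changeux (MWC) allosteric activity curves and
    thermodynamic (states-and-weights) production functions for
    auto-activation, mutual repression (toggle switch) and feed-forward loop
    motifs, together with the analysis toolkit needed to study them: fixed
    points and stability, bifurcation diagrams over effector concentration,
    bistability maps and necessary conditions, hysteresis protocols,
    relaxation timescales, separatrices and basins of attraction, and
    closed-form step-response delay theory for feed-forward loops (offset
    function, average delay, logic-gate sweeps, pulse detection and
    continuous-signal responses).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
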