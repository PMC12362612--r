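Package: fatecontrol
Title: Adaptive Sequestration-Based Feedback Control of Multistable Gene Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for an adaptive biomolecular
    feedback controller built from an incoherent feedforward loop and
    molecular sequestration, applied to multistable gene regulatory
    networks (toggle switch, mutual activation, toggle with
    self-activation). Provides declarative model specifications from which
    both deterministic ODE right-hand sides and exact stochastic
    simulation (Gillespie) reaction systems are derived; quasi-steady-state
    reduction of the controller; nullcline, equilibrium and stability
    analysis; the fast-sequestration filter-cascade approximation of the
    controller output; cell-fate classification of stochastic ensembles;
    and parameter-scan drivers with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
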