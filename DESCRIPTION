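Package: navfit
Title: Markov-State Modeling and Multi-Protocol Fitting of Cardiac Sodium
    Channel Kinetics and State-Dependent Drug Block
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds, simulates, and fits Markov-state models of the cardiac
    voltage-gated sodium channel (Nav1.5) and its state-dependent interaction
    with class I antiarrhythmic drugs such as flecainide. Provides the 8-state
    gating scheme with voltage-dependent transition rates and microscopic
    reversibility enforced by construction, charged/neutral drug-bound scheme
    extensions with Eyring voltage-dependent affinities and cycle closure,
    exact matrix-exponential simulation of piecewise-constant voltage-clamp
    protocols, the summary statistics used in channel electrophysiology
    (availability, activation, recovery, decay times, mean open time), a
    normalized multi-objective cost with fork-join protocol evaluation, a
    bounded Nelder-Mead optimizer with sequential/factorial scheduling and
    perturbation restarts, a robustness (perturb-and-refit) study, and
    synthetic dataset generation for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    minpack.lm,
    parallel,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
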