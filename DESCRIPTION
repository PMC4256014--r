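Package: sacwave
Title: Reaction-Diffusion Modelling of Cholinergic Retinal Waves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of stage II (cholinergic) retinal waves in
    the developing retina. Starburst amacrine cells are modelled as
    Morris-Lecar excitable units with a slow after-hyperpolarisation cascade,
    coupled through the volume release and diffusion of acetylcholine. The
    package integrates the stochastic reaction-diffusion system on 1D/2D
    lattices with an operator-splitting scheme (locally one-dimensional
    Crank-Nicolson diffusion, two-stage Runge-Kutta reaction), detects and
    measures spatiotemporal wave events (size, duration, speed, inter-wave
    intervals, correlation structure), constructs travelling wave fronts of
    the fast subsystem to map excitability thresholds and the absolute
    refractory period, and maps the wave model onto the Drossel-Schwabl
    forest-fire model to delineate the parameter region where avalanche
    (power-law) wave statistics are expected.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Matrix,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
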