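Package: mirswitch
Title: Bistable Switch Dynamics of the Myc/E2F/miR-17-92 Feedback Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dynamical analysis of a two-variable model of the Myc/E2F
    protein module coupled to the miR-17-92 microRNA cluster: an
    autocatalytic positive feedback loop under hyperbolic microRNA
    inhibition, with protein-driven microRNA transcription closing a
    negative loop.  Provides steady-state solution and linear stability
    classification, one-parameter bifurcation sweeps with saddle-node and
    Hopf location, two-parameter regime maps (monostable, bistable,
    excitable, oscillatory; bistable versus one-way switch), deterministic
    fixed-step Runge-Kutta simulation of signal-response protocols
    (constant, pulse, step), and stochastic ensembles driven by Gaussian
    white noise on the stimulus, with fraction-of-transition curves,
    plateau fractions, and response times.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
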