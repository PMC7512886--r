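Package: lovechaos
Title: Chaos Diagnostics for a Periodically Forced Love-Affair Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulator and chaos-diagnostics toolkit for an extended
    Romeo-and-Juliet love model, a planar nonlinear system in which the
    two state variables are the signed love/hate levels of the couple and
    a sinusoidal forcing term represents positive and negative advice from
    a third party. Provides fixed-step Runge-Kutta integration with exact
    stroboscopic sampling, period detection from Poincare sections,
    power-spectrum peak analysis, maximal Lyapunov exponents by the
    Benettin tangent-vector method, bifurcation-diagram parameter sweeps,
    fixed-point classification for the underlying linear model, and a
    command-line interface. As the self-feeling coefficient of one partner
    is varied the model passes through a period-doubling cascade
    (period 1, 2, 4, ...) into single-scroll and double-scroll chaotic
    attractors, and the toolkit classifies these regimes automatically.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
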