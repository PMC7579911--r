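Package: dynenz
Title: Pareto-Optimal Dynamic Enzyme Activation in Kinetic Pathway Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for computing time-varying enzyme-activation strategies in
    kinetic models of metabolic pathways by solving multi-objective nonlinear
    optimal control problems. Implements a two-phase numerical strategy:
    control vector parameterization with a hybrid scatter-search/local method,
    followed by full trapezoidal collocation with symbolically assembled
    derivatives and Lagrange-multiplier (adjoint) extraction. Pareto fronts
    are traced with the epsilon-constraint method. Ships three benchmark
    pathway models (a three-step linear pathway, yeast central carbon
    metabolism during diauxic shift, and B. subtilis central carbon metabolism
    under substrate shifts), plus analytic fixtures, solution-multiplicity
    ensembles, constraint sweeps and multiplier-based sensitivity reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    compiler,
    deSolve,
    Matrix,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
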