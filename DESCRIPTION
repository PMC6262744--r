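Package: selfthin
Title: Self-Thinning Frontiers and Site Carrying Capacity in Mixed Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates self-thinning frontiers and site maximum carrying
    capacity (maximum stand density index) in mixed-species forests by seven
    contrasting strategies: static plot-level linear mixed-effects, linear
    quantile mixed-effects (asymmetric Laplace likelihood with Gauss-Hermite
    quadrature), stochastic frontier regression with plot random effects,
    tree-level density-index quantile fits, and three dynamic strategies
    built on remeasured plots (a closed-form size-density ODE model, a
    negative binomial mortality model, and a first-measurement trajectory
    model). Derives Reineke-type self-thinning lines from every fit, predicts
    plot-level maximum stand density index at a reference diameter, compares
    strategies with Scheffe's simultaneous test and a compact letter display,
    and models carrying capacity on diversity, stand-structure and
    bioclimatic covariates. Includes a synthetic plot-network generator with
    known truth so that every fitter is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme,
    glmmTMB,
    minpack.lm,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
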