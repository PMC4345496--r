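Package: constraintvalue
Title: Constraint Value Analysis and Experimental Design for Large ODE Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies how much information each quantitative constraint
    (a measured level, period, peak time, amplitude or peak ratio with a
    standard error) contributes to the calibration of a parametrized ODE
    model.  Constraints are linearized in logged parameters, normalized by
    their standard errors, and ranked by constraint value: the norm of the
    component of a linearized constraint orthogonal to the span of the
    constraints already applied.  The package analyses the induced
    optimization geometry (Fisher information spectrum, singular-value
    interlacing when a constraint is added, the ellipsoidal approximate
    solution set), generates synthetic sloppy constraint ensembles with
    prescribed geometric decay, and ranks candidate experiments by the
    value of the new constraint they would contribute.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
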