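Package: t3pcovr
Title: Tucker3 Principal Covariates Regression for Coupled Two-Way and
    Three-Way Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits the Tucker3-PCovR model for coupled data in which a
    two-way predictor matrix (objects x covariates) explains a three-way
    criterion array (objects x attributes x sources). Predictors are
    reduced to a small number of components that simultaneously
    summarize the predictor block and, through a Tucker3 decomposition
    of the regression weights, predict the criterion array. Includes an
    alternating least squares estimator with rational, perturbed and
    random multi-start initialization, convex-hull (CHULL) model
    selection over Tucker3 complexities, varimax rotation with exact
    counterrotation of the core array, and coordinate constructions for
    joint, interactive, triplot, regression-weight and interpolation
    biplots with graded axis scales. A synthetic-data generator with
    known ground truth supports recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
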