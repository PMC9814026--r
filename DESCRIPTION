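Package: coxaghq
Title: Approximate Bayesian Inference for Cox Models via Partial Likelihood
    and Adaptive Quadrature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Approximate Bayesian inference for Cox proportional hazards
    models based on the partial likelihood.  The additive predictor may
    contain linear covariate effects, penalized cubic B-spline smooth
    effects, i.i.d. Gaussian group frailties and Matern spatial random
    effects.  Inference combines a Tierney-Kadane Laplace approximation
    for the variance parameters with adaptive Gauss-Hermite quadrature,
    yielding a Gaussian-mixture approximation to the posterior of the
    latent field from which independent samples are drawn.  Includes
    synthetic-data generators for simulation studies with piecewise
    baseline hazards, a gradient-based MCMC sampler targeting the exact
    joint posterior for validation, and Kolmogorov-Smirnov comparison
    utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
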