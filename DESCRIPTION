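Package: demobo
Title: Bayesian Optimization for Expensive Demographic Inference Likelihoods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequential model-based (Bayesian) optimization for expensive
    black-box objectives such as negative log-likelihoods of demographic
    models fitted to site frequency spectra. Provides Gaussian-process
    surrogate regression with the four half-integer Matern-family kernels,
    closed-form expected improvement, probability of improvement and
    log-expected-improvement acquisitions, leave-one-out cross-validation
    for automatic prior selection, an ensemble pipeline that mixes
    acquisitions by a fair coin, BFGS local polish, a toy single-population
    site-frequency-spectrum Poisson objective with dadi/moments-style
    spectrum file input/output, and a replication harness that aggregates
    convergence traces across seeded runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
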