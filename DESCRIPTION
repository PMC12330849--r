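Package: spectraldcm
Title: Spectral Dynamic Causal Modelling of Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Estimation of effective connectivity between brain regions from
    resting-state fMRI by spectral dynamic causal modelling.  Composes linear
    neural-mass regions with balloon-model hemodynamics and a BOLD observation
    equation, predicts cross-spectral densities from the linearized system,
    estimates data cross-spectra by maximum-likelihood multivariate
    autoregressive (MVAR) fits, inverts models with a variational Laplace
    (free-energy) scheme, and compares candidate connectivity structures by
    their free energy.  Includes a seeded generator of synthetic BOLD time
    series from the full nonlinear model for validation and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
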