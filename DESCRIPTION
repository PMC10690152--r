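Package: pptmstats
Title: Statistical Analysis of Passive Particle-Tracking Microrheology in
    Heterogeneous Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for passive particle-tracking microrheology of extremely
    heterogeneous soft materials such as flake-burdened airway mucus. Each
    tracked bead's position time series is decomposed into a fractional
    Brownian motion (fBm) signal, high-frequency static and dynamic
    localization noise, and low-frequency drift. A least-squares predictor
    followed by an exact Gaussian maximum-likelihood corrector (the fARMAs
    model) yields a denoised two-parameter mean-squared-displacement
    classifier (alpha, D_alpha) per bead together with its covariance.
    Ensembles of classifiers are clustered with finite normal mixtures and
    BIC model selection, tested for homogeneity with Cochran's Q, and mapped
    to dynamic moduli through the generalized Stokes-Einstein relation using
    three cluster-averaging protocols appropriate for homogeneous and
    heterogeneous clusters. Includes an exact circulant-embedding simulator
    for synthetic trajectory ensembles with localization noise, motion blur,
    drift, and stuck-bead controls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    mclust,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
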