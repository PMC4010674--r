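Package: cmcfield
Title: Canonical-Microcircuit Neural-Field Models for ECoG Cross-Spectral
    Densities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits a four-population canonical-microcircuit neural-field model
    to multi-site electrocorticographic cross-spectral densities. The model
    couples spiny stellate cells, inhibitory interneurons and deep and
    superficial pyramidal cells on a one-dimensional cortical patch through
    exponentially decaying horizontal kernels with conduction delays, and
    predicts complex cross-spectra at bipolar recording sites through Gaussian
    lead fields. Analytic spatiotemporal transfer functions, a delayed
    stochastic field simulator for validation, condition-specific (e.g.
    stimulus-contrast) modulation of parameter subsets, variational-Laplace
    model inversion with free-energy scoring, and fixed-effects Bayesian model
    comparison across a factorial model space (including a neural-mass
    restriction) are provided, together with a synthetic-data generator that
    emulates multi-condition visual-contrast experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
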