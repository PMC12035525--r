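Package: lianasignal
Title: Mechanistic Modelling and Detectability of the Liana Spectral Signal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward and inverse radiative-transfer modelling of liana-infested
    forest canopies. Couples a generalized plate-model leaf simulator with a
    two-layer four-stream canopy model in which the liana leaf layer sits on
    top of the host tree crown, inverts leaf and canopy spectra in a Bayesian
    framework using a differential-evolution MCMC sampler, quantifies the
    spectral separability of liana-infested and liana-free canopies with
    Gaussian Kullback-Leibler divergence (per wavelength, integrated, and
    after sensor band convolution), runs trait-swap sensitivity experiments,
    and simulates clustered-infestation scenes to study how spatial resolution
    and liana aggregation interact to limit detectability. Ships synthetic
    trait and scene generators so the full pipeline runs without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    pracma,
    purrr,
    Rcpp,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    EBImage,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
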