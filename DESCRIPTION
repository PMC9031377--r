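Package: resharp
Title: Spectral Sharpening and Resonance-Frequency Estimation for
    Microwave Resonant Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to numerically sharpen the return-loss response of
    microwave resonant sensors and to estimate the resonance frequency
    with sub-sampling-step accuracy.  Implements three estimators built
    on discrete-time Fourier transform pairs of the return-loss phase: a
    single-step Fourier-pair algorithm, an iterative Fourier-pair
    algorithm, and a MUSIC pseudospectrum estimator, together with a
    shared preprocessing chain (sweep averaging, endpoint flattening,
    baseline removal, alpha-band and beta-support selection).  Includes
    an asymmetric-Gaussian synthetic return-loss generator with an
    acquisition-noise model, Monte Carlo benchmarking of the estimators
    by percentage error, blind dispersion characterisation of the
    estimate on measured traces, readers for two-column CSV and
    Touchstone one-port S-parameter files, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
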