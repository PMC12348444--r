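Package: fluocascade
Title: Monte Carlo Fluorescence Cascade Transport and Quantum Yield Retrieval
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward Monte Carlo solver of the fluorescence radiative transfer
    equation for layered turbid media with the full re-absorption/re-emission
    cascade, coupled to an analytic integrating-sphere detection model.
    Includes a three-component Gaussian-mixture model of the intrinsic
    emission probability distribution, Levenberg-Marquardt retrieval of the
    fluorescence quantum yield and emission parameters from reflectance and
    transmission spectra, classical overlap-integral re-absorption
    corrections, cascade diagnostics, and deterministic synthetic fixtures
    emulating a Rhodamine-6G-like dye in scattering cuvette samples.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
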