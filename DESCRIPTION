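Package: petmrac
Title: Simulation Framework for MR-Based Attenuation Correction in Dynamic Brain PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthetic evaluation pipeline for MR-based attenuation correction
    (MRAC) methods in dynamic brain PET. Generates digital head phantoms with a
    bone shell, air sinuses and striatal/cerebellar regions; builds candidate
    511 keV attenuation maps by multi-atlas majority voting over pseudo-CT
    databases (MaxProb), zero-echo-time-like histogram segmentation with a
    continuous bone calibration, and a degraded transmission-like reference;
    propagates attenuation-map errors through a 2D parallel-beam dynamic PET
    simulation with Poisson counting noise and OSEM reconstruction; quantifies
    binding potential and relative delivery with the simplified reference
    tissue model via basis-function fitting (receptor parametric mapping); and
    evaluates accuracy and precision with bias maps, relative bias, Deming
    regression, Spearman correlation, Friedman tests with Dunn-adjusted
    post-hoc comparisons, and time-activity-curve bias curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    graphics,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
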