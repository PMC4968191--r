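Package: spidiff
Title: Simulation, Calibration and Model Validation for Single-Particle
    X-Ray Diffraction Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for single-particle imaging (SPI) experiments at X-ray
    free-electron lasers: flat pixel-array detector geometry and
    reciprocal-space mapping, photon-counting detector calibration
    (pedestal, common-mode and gain corrections, ceil-rule photonization,
    gain estimation from flat-field single-photon histograms), a synthetic
    diffraction-data generator (homogeneous-sphere and icosahedral
    blob-shell scattering models with Poisson shot noise, fluence jitter,
    beam-centre drift, beamstop and panel gaps), homogeneous-sphere size
    fitting by profiled Poisson likelihood, radial hit-versus-blank signal
    analysis, the Poisson surprise statistic with its analytic mean,
    standard deviation and z-score for validating recorded scattering
    against a particle model, and CXI-flavoured HDF5 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    rhdf5,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
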