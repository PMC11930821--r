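Package: dcsflow
Title: Diffuse Correlation Spectroscopy Analysis of Cerebral Blood Flow Variability
Version: 0.1.0
Authors@R:
    person("dcsflow", "developers", email = "dcsflow@example.org", role = c("aut", "cre"))
Description: Tools for analysing diffuse correlation spectroscopy (DCS)
    recordings of cerebral hemodynamics. Implements the semi-infinite
    correlation diffusion forward model with Brownian scatterer dynamics,
    nonlinear recovery of a blood flow index (CBFi) from measured intensity
    autocorrelation curves g2(tau), windowed coefficient-of-variation trend
    inference, low-frequency Welch spectral analysis, accelerometry-based
    motion controls, ultrasound region-of-interest echogenicity ratios, and a
    fully seeded synthetic-data generator (including a viscosity-controlled
    Brownian optical phantom) for validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
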