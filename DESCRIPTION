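Package: nirsdcs
Title: Hybrid Time-Domain NIRS and Diffuse Correlation Spectroscopy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and inversion for hybrid diffuse-optics
    monitoring of tissue hemodynamics. Simulates time-domain near-infrared
    spectroscopy photon time-of-flight histograms (semi-infinite diffusion
    theory convolved with an instrument response function, Poisson counting
    noise) and diffuse correlation spectroscopy intensity autocorrelation
    curves (correlation-diffusion g1 with the Siegert relation), fits them
    for absolute absorption and reduced scattering, hemoglobin
    concentrations, tissue oxygen saturation and a blood-flow index, and
    extracts vascular-occlusion-test biomarkers (desaturation and
    resaturation slopes, hyperemic areas under the curve) plus Fick-law
    metabolism indices. Includes quality-assessment-phase evaluation,
    instrument-response trending, and precision and agreement statistics
    (coefficients of variation, test-retest, Bland-Altman, rank tests).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils,
    graphics,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, knitr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
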