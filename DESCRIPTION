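Package: nirspain
Title: Simulation and Analysis of fNIRS Pain-Modulation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for functional near-infrared spectroscopy (fNIRS) studies of
    pain modulation by breathing practice. Covers the full chain from raw
    two-wavelength intensities to publishable statistics: modified Beer-Lambert
    conversion to oxy-/deoxyhemoglobin, AR-prewhitened robust first-level GLM
    with a canonical hemodynamic response, group-level mixed-effects activation
    maps with false-discovery-rate control, band-limited robust functional
    connectivity with Fisher-Z scoring, heart-rate-variability (SDNN)
    extraction from the optical signal, and elastic-net selection of
    connectivity edges that predict thermal pain thresholds. Ships a forward
    simulator of the complete study design (thermal quantitative sensory
    testing, physiological oscillations, serially correlated noise, planted
    activation, connectivity and brain-behavior coupling) so that every
    analysis stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    data.table,
    glmnet,
    jsonlite,
    lme4,
    lmerTest,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
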