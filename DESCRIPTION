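Package: tigertrend
Title: Standardizing Capture-Recapture Density Estimates with
    Meta-Regression and Landscape Population Projection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for comparing animal density estimates across
    camera-trap studies that used different estimation methods. Simulates
    spatially explicit capture-recapture surveys with half-normal
    detection; fits the closed-population M0 abundance model and a
    maximum-likelihood spatial capture-recapture (SCR) model with habitat
    masks and multi-session parameter sharing; re-standardizes published
    non-spatial capture-recapture densities by replacing study-specific
    buffers with an SCR-derived standard buffer; meta-regresses log
    standardized densities on habitat, disturbance and temporal
    covariates with landscape random effects and known relative sampling
    error; and projects habitat-specific densities onto landscape
    forest-area tables to obtain subpopulation sizes, breeding-female
    counts and secure-source-population status.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    lme4,
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
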