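Package: lesionkinetics
Title: Logistic Growth and Regression Kinetics of Induced Hepatic
    Lesions from Longitudinal CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative pipeline for longitudinal CT assessment of
    induced hepatic lesions in a large-animal model: label-map volumetry
    (voxel counts, volumes, exposed-face surface areas, island removal),
    a two-phase logistic growth/regression model with a cell-to-volume
    conversion, nonlinear least-squares phase fitting with parameter
    recovery diagnostics, summary reporting (phase-wise linear rates,
    growth extrapolation past the breakpoint, take rates), and a seeded
    synthetic-cohort generator emulating a weekly-scanned multi-animal
    inoculation study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    RNifti,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
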