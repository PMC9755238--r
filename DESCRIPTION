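Package: claustrumdev
Title: Neonatal Claustrum Morphometry, Microstructure and Structural Covariance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for claustrum structure in neonatal brain MRI.
    Builds claustrum control masks (white-matter frame and interior
    "claustrum-controlled" segmentation) from label volumes, extracts
    macrostructural (absolute and total-brain-volume-relative volume) and
    microstructural (mean diffusivity, fractional anisotropy) region-of-interest
    outcomes, and runs cross-sectional general linear models with partial
    eta-squared effect sizes, minimal scan-age-gap case-control matching,
    paired longitudinal tests, random-intercept mixed models, and structural
    covariance network comparison via Fisher r-to-z with false discovery rate
    correction. Includes a seeded synthetic cohort and phantom generator that
    emulates a preterm/term neonatal imaging study for parameter-recovery
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
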