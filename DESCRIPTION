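Package: opmapr
Title: Cardiac Optical Mapping Analysis: Activation, Conduction Velocity,
    and Slow-Conduction Region Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for voltage-sensitive-dye optical mapping
    movies of cardiac tissue. Converts fluorescence movies into local
    activation time maps (maximum-upstroke detection with sub-frame
    interpolation), per-pixel conduction velocity vectors (local polynomial
    surface fit of the activation surface, inverse-gradient velocity),
    and slow-conduction region reports (thresholding, 4-connectivity
    component labeling, area quantification). Includes a synthetic movie
    generator based on an eikonal wavefront solver that provides ground
    truth for validation, a generator for clustered study tables, and
    study-level statistics: linear mixed-effects models with animal as a
    random effect, mean-centered marginal Wald contrasts, intraclass
    correlation, design effect, and effective sample size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    emmeans,
    jsonlite,
    lme4,
    signal,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
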