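Package: frogs
Title: Region-Specific Fetal Growth Centiles and Chart Validation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a region-specific fetal growth standard built by
    rescaling the Hadlock log-quadratic fetal weight curve to a local term
    mean birthweight (the proportionality approach), with centiles generated
    from a constant coefficient of variation and optional adjustment for
    fetal sex. Provides exact centiles for each gestational day, z-scores,
    and measurement-error estimate ranges; comparator chart families
    (week-resolution unisex charts, empirical birthweight charts, and
    generic centile-bracket lookup tables); the FIGO-style two-step chart
    validation (distributional calibration diagnostics and outcome-based
    comparison of non-overlapping small-for-gestational-age populations via
    relative risks with log-method confidence intervals and Wilson score
    intervals); a synthetic singleton birth-cohort simulator with
    controllable growth-restriction structure; and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
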