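Package: rflbounds
Title: Attrition Diagnostics and Random Forest Lee Bounds for Randomized Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partial-identification tools for two-arm randomized trials with
    missing outcome data. Provides attrition accounting and power-loss
    diagnostics, MCAR/MAR validation regressions, Horowitz-Manski worst-case
    bounds, Lee trimming bounds (unconditional and conditional on discrete
    cells) with bootstrap outer confidence intervals, and a Random Forest Lee
    Bounds procedure that tightens bounds by conditioning on covariates --
    including continuous ones -- selected by a cross-validated
    permutation-importance screen against a random benchmark variable and
    discretized by an entropy-based decision tree. Includes a seeded
    generator of synthetic two-arm trials with configurable MCAR/MAR/MNAR
    attrition mechanisms and a simulation-study harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    foreign,
    graphics,
    jsonlite,
    MASS,
    optparse,
    ranger,
    sandwich,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
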