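Package: rootzn
Title: Root Efficiency Analysis of Zinc Uptake in Rice
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing genotype differences in tolerance of
    zinc-deficient soils from plant-level field-trial data.  Fits
    offset-exponential models to cumulative Zn uptake and root surface
    area time-series, derives the root-efficiency statistic
    RE = (dU/dt)/RSA, decomposes group uptake differences into
    root-growth and root-efficiency contributions by counterfactual
    curve swaps, and provides planting-density fold-change and
    shoot-to-root Zn retranslocation analyses, ANOVA-protected LSD
    comparisons, and a synthetic-trial generator emulating the
    randomized-block field design so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
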