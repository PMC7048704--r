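Package: rmnch
Title: Equity and Coverage Analysis for RMNCH Interventions
Version: 0.1.0
Authors@R:
    person("RMNCH", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing equity and coverage of reproductive,
    maternal, newborn and child health (RMNCH) interventions from
    household-survey microdata. Provides a synthetic DHS-style survey
    generator with known ground-truth coverage gradients, asset-index
    wealth-quintile construction by principal components, survey-weighted
    coverage estimation, the Composite Coverage Index, two-stratum equity
    gaps with a coverage-by-inequity pattern classification, annualized
    rate-of-change projection of coverage, and a simplified lives-saved
    engine translating coverage scale-up into deaths averted using a
    residual-hazard combination of linked interventions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
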