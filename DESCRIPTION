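Package: svymine
Title: Survey-Weighted Association Rule Mining of Multimorbidity Combinations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Discovers chronic-condition combinations in complex-survey
    microdata with a weighted Apriori search, estimates design-based
    (Taylor-series linearized) prevalence, observed-to-expected prevalence
    ratios (lift), per-combination medical expenditures and poor-health
    burden, prunes redundant combinations with a minimum-improvement rule,
    and fits survey-weighted logistic regression for age-race-sex adjusted
    odds ratios of poor self-rated health.  Includes a synthetic generator
    that emulates a stratified two-PSU-per-stratum household survey with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
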