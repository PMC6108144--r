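Package: elmtarget
Title: Multi-Factor Risk Estimation and Program Targeting for Early-Life Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step workflow for allocating a fixed intervention budget to
    births at highest risk of infant death. Step one fits a hierarchical
    Bayesian logistic model of per-birth mortality risk over maternal age,
    maternal education, household wealth and district, including all
    interaction terms, with effects classified fixed or random by their
    number of observed levels. Step two cross-classifies births into
    demographic-by-geography subgroups, ranks them by average estimated
    risk and greedily fills a budget (20 percent of births by default)
    under district-, state- or national-level policy constraints, with
    fractional inclusion of the marginal subgroup so coverage is exact.
    Includes a synthetic DHS-style cohort generator with known ground-truth
    risk for validation, evaluation tools (deaths-captured rates,
    exceedance shares, district summaries, census projections) and a
    reproducible pipeline with file-based inputs and outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
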