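Package: trastucost
Title: Cost-Minimization Modelling of Intravenous Versus Subcutaneous
    Trastuzumab in Early Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for cost-minimization analysis of
    route-of-administration switches in adjuvant trastuzumab. Models three
    treatment scenarios (weight-based intravenous dosing, fixed-dose 600 mg
    subcutaneous dosing, and intravenous during chemotherapy followed by
    subcutaneous), converting weekly infusion blocks to every-three-weeks
    injections at a 3:1 ratio. Accounts for drug acquisition cost,
    preparation-stage waste, pharmacy preparation labour and infusion-chair
    occupancy; solves the break-even mean body weight at which fixed-dose
    subcutaneous treatment becomes cheaper than weight-based intravenous
    treatment; compares scenarios with one-way ANOVA and Bonferroni-adjusted
    post-hoc tests; and generates synthetic patient cohorts calibrated to
    published aggregate structure for reproducible desk-scale analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
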