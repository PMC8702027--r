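Package: sedscreen
Title: Bioactivity-Based Hazard Screening and Remediation Analysis for
    Contaminated Sediments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for in vitro concentration-response
    screening of environmental sediment extracts. Fits nonlinear logistic
    concentration-response curves to vehicle-scaled plate data and derives
    points of departure (PODs) by the vehicle-band crossing rule; integrates
    PODs into Toxicological Priority Index (ToxPi) scores with per-cell-type
    and overall sample rankings; tests spatial association of chemical and
    biological features with a permutation Mantel test and interpolates maps
    by ordinary kriging with a spherical semivariogram; cross-predicts
    bioactivity from chemistry (and vice versa) by leave-one-out
    cross-validated ridge regression; computes hazard index and cancer risk
    from PAH concentrations against screening levels; and compares
    traditional (chemical risk-based) with bioactivity-based remediation
    goals. Includes a synthetic-data generator that emulates the statistical
    structure of a post-disaster sediment screening study, with exported
    ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
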