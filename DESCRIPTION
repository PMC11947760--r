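Package: wmhboot
Title: Matched-Bootstrap Group Contrasts for White Matter Hypointensity Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing white matter hypointensity (WMH) burden
    between demographic groups in observational cohorts using repeated
    covariate-matched subsampling of the larger group. Provides a synthetic
    cohort generator emulating the marginal structure of multi-site
    clinical/MRI aging cohorts, stratified nearest-neighbour matching with
    balance diagnostics, baseline linear and longitudinal random-intercept
    models of ordinal severity or log lesion volume, percentile confidence
    intervals of bootstrap t-statistics, and vascular-risk-factor
    adjustment comparisons (attenuation and suppression analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    lme4,
    optparse,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
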