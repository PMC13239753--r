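Package: aortanorm
Title: Allometric Normalization of Echocardiographic Aortic Root Dimensions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for indexing echocardiographic aortic root dimensions
    (annulus, sinuses of Valsalva, proximal ascending aorta) by a
    multivariate allometric model of the form
    Yp = a * b^gender * age^x * height^y * weight^z, fitted by stepwise
    log-linear regression, as an alternative to ratiometric body-surface-area
    indexation. Includes cohort construction (propensity-score matching of
    two populations, randomized construction/validation splits, age-group
    stratification), correction-efficacy assessment via residual-correlation
    criteria, reference-interval estimation for corrected values,
    measurement-reliability analysis (Bland-Altman, intraclass correlation),
    and a synthetic-cohort generator so the whole pipeline can be exercised
    without patient-level data.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
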