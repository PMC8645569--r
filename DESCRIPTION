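Package: ocltools
Title: Schedules, Scoring, Simulation and Score Equating for the One Card
    Learning Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Toolkit for the One Card Learning (OCL) continuous visual
    recognition test in its 80-trial and reduced-difficulty 48-trial forms.
    Generates trial schedules under the target/lure/foil card-selection and
    interleaving constraints, administers and scores sessions on the
    arcsine-square-root proportion-correct scale, simulates respondents and
    cohorts calibrated to published group moments, and implements the
    accompanying psychometric battery: Glass's delta and Cohen's d effect
    sizes, intraclass correlation with within-subject variability,
    Hotelling T-squared profile analysis, mixed ANOVA with sphericity
    diagnostics, floor/ceiling detection, and equipercentile equating
    between forms with loglinear presmoothing and bootstrap standard
    errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
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
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
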