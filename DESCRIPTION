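Package: actikids
Title: Device-Measured Movement Behaviours and Trajectories in Young Children
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the full device-based movement-behaviour pipeline in
    early childhood cohorts: simulation of raw tri-axial hip accelerometry
    (30 Hz) with ground truth, 15-second window feature extraction (25
    time- and frequency-domain features on the vector magnitude), a
    500-tree random-forest activity classifier with leave-one-subject-out
    validation for five activity classes, non-wear detection (vector
    magnitude SD < 13 mg for at least 30 consecutive minutes), valid-day
    and valid-subject rules, age-specific 24-hour movement guideline
    scoring, and restricted-cubic-spline mixed models with marginal means
    for sedentary time and physical activity trajectories from ages two to
    seven.
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
    lme4,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
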