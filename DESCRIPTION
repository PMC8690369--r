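Package: relapsetraj
Title: Relapse Trajectories from Patient-Registry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies schizophrenia relapse episodes from registry-shaped
    event data (hospitalisations, outpatient psychiatric visits, antipsychotic
    dispensations) using proxy definitions, builds recurrent-event
    counting-process data with time-varying covariates, and quantifies the
    risk of and time to the next relapse as a function of prior relapse count
    via cause-specific Cox models and Aalen-Johansen cumulative incidence
    with death as a competing risk. Includes a synthetic-registry simulator
    with known ground truth for end-to-end validation.
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
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
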