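Package: lifeage
Title: Mortality-Anchored Effective-Age Scoring and Single-Arm Evaluation of Lifestyle Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes a "Life Age" risk-communication score: chronological age
    plus signed year offsets derived from modifiable lifestyle factors (body
    mass index, smoking, alcohol, Mediterranean-diet adherence, physical
    activity) via a Gompertz-hazard effective-age conversion of relative
    risks, plus a psychosocial well-being component (life satisfaction,
    combined mood, perceived stress, sleep) mapped to years by distance from
    population norms. Includes questionnaire scorers, paired pre/post
    evaluation statistics (paired t test, exact Wilcoxon signed-rank,
    cohort summaries, sample-size and power calculations), and a seeded
    synthetic paired-cohort generator so the whole pipeline is testable
    without participant data.
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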