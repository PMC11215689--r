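Package: issq
Title: Individualized Cancer Screening Schedules via Linear Q-Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for learning individualized follow-up schedules for
    screen-detected pulmonary nodules with reinforcement learning. Generates
    synthetic nested case-control screening cohorts with configurable
    covariate marginals and nodule growth dynamics, enumerates legal
    sequential follow-up scenarios (immediate work-up, 3-month or annual
    repeat CT, discontinuation), scores them with a reward function
    penalizing misdiagnosis, missed diagnosis, delayed diagnosis and repeat
    testing, fits backward-induction linear Q-functions with state-action
    interactions in eight state-variable variants, and benchmarks the fitted
    policies against editable rule-based guideline tables with head-to-head
    and subgroup reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
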