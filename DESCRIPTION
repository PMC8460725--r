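Package: clockbind
Title: Action Binding from Libet-Clock Timing Judgements and Its Relation
    to Delusional Ideation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for intentional-binding experiments that
    measure the perceived time of a voluntary keypress with a modified
    Libet clock: participants aim at the 12 o'clock position and judge
    whether the press fell before, at, or after it.  The package derives
    perceived and actual keypress times from trial-level timestamps,
    applies MAD-median participant exclusion, estimates the action-binding
    effect (operant minus baseline condition) with Cohen's dz/ds effect
    sizes, models the testing-order carryover via trial-by-trial slopes
    and a leave-first-n-trials-out scan with a significance-based cutoff,
    scores the 21-item Peters Delusions Inventory, and relates delusional
    ideation to per-participant binding strength through a seeded
    percentile-bootstrap Pearson correlation.  A synthetic-cohort
    generator reproduces the task's statistical structure (aiming noise,
    acquisition until a fixed count of 'at-12' trials, exponentially
    decaying carryover, trait-coupled binding) so the whole pipeline is
    testable by parameter recovery without the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
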