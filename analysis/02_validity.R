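#!/usr/bin/env Rscript
# Validity of the before/at/after timing judgement: the physical press
# should be earliest on 'before 12' trials, intermediate on 'at 12',
# latest on 'after 12', and a negative aiming bias should produce more
# 'before' than 'after' responses.

library(clockbind)

trials <- read_trials("results/cohort/trials.csv")
rep <- response_validity_report(trials)

cat("mean actual keypress time (ms) by response category:\n")
print(as.data.frame(rep$category_means), row.names = FALSE)
cat("\npaired contrasts (two-tailed):\n")
print(as.data.frame(rep$contrasts), row.names = FALSE)
cat("\nbefore/after trial-count contrast:\n")
print(as.data.frame(rep$count_contrast), row.names = FALSE)
cat("\n(approximate) binding within before/after trials, one-tailed:\n")
print(as.data.frame(rep$binding_in_category), row.names = FALSE)

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(
  list(category_means = as.data.frame(rep$category_means),
       contrasts = as.data.frame(rep$contrasts),
       count_contrast = as.data.frame(rep$count_contrast),
       binding_in_category = as.data.frame(rep$binding_in_category)),
  "results/validity.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("\nwrote results/validity.json\n")
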