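#!/usr/bin/env Rscript
# Testing-order effect: trial-by-trial development of the perceived
# keypress time (OLS slopes per condition x group) and the
# leave-first-n-trials-out scan that locates the cut-off from which the
# between-group binding difference stays non-significant.

library(clockbind)

trials <- read_trials("results/cohort/trials.csv")
sm <- build_summaries(trials)
kept <- with(mad_median_exclusions(sm), participant_id[!flagged])

slopes <- condition_slopes(sm, participants = kept)
st <- slope_group_tests(slopes)
cat("one-sample slope tests (ms per 'at-12' trial, vs 0, two-tailed):\n")
print(as.data.frame(st$one_sample), row.names = FALSE)
cat("\nbetween-group slope contrasts:\n")
print(as.data.frame(st$between_groups), row.names = FALSE)

scan <- leave_first_n_scan(sm, n_max = 30, participants = kept)
cutoff <- cutoff_from_scan(scan, alpha = 0.05, horizon = 30)
cat(sprintf("\nscan cutoff n*: %s (order effect non-significant from there through the horizon)\n",
            ifelse(is.na(cutoff), "none", cutoff)))

utils::write.csv(scan$table, "results/order_scan.csv", row.names = FALSE)
jsonlite::write_json(
  list(one_sample = as.data.frame(st$one_sample),
       between_groups = as.data.frame(st$between_groups),
       cutoff = cutoff, alpha = 0.05, horizon = 30),
  "results/order_scan.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote results/order_scan.csv and results/order_scan.json\n")
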