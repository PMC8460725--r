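#!/usr/bin/env Rscript
# Delusional ideation vs action binding: PDI-21 overall scores joined
# with the per-participant binding strength (trial-level t with the
# first 10 'at-12' trials of each condition dropped), boxplot-rule
# exclusion on both variables, one-tailed Pearson correlation with a
# seeded percentile-bootstrap 95% CI.

library(clockbind)

trials <- read_trials("results/cohort/trials.csv")
pdi <- read_pdi("results/cohort/pdi.csv")
sm <- build_summaries(trials)
kept <- with(mad_median_exclusions(sm), participant_id[!flagged])
est <- binding_estimates(sm, n_drop = 10, participants = kept)

res <- delusion_binding_analysis(est, pdi, n_boot = 2000, seed = 20260301)
co <- res$correlation
led <- res$ledger
cat(sprintf("Pearson r = %.2f, p = %.3f (one-tailed), 95%% CI [%.2f %.2f], bootstrap (%d resamples)\n",
            co$r, co$p, co$ci_low, co$ci_high, co$n_boot))
cat(sprintf("n = %d (%d after MAD-median - %d incomplete PDI - %d boxplot outliers)\n",
            led$n_used, led$n_in, led$n_incomplete, led$n_boxplot))

utils::write.csv(res$data, "results/correlation_scatter.csv",
                 row.names = FALSE, na = "")
jsonlite::write_json(
  list(correlation = unclass(co), ledger = led),
  "results/correlation.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote results/correlation.json and results/correlation_scatter.csv\n")
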