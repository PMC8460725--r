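# Hand-built trial tables and convenience configs used across the suite.

# A configuration with every noise source switched off; individual
# parameters can be overridden.
noise_free_config <- function(...) {
  args <- list(...)
  base <- list(aim_sd = 0, aim_bias = 0, drift_slope = 0,
               carryover_into_ao = 0, carryover_into_as = 0,
               binding_sd = 0, baseline_shift_sd = 0,
               pdi_binding_rho = 0, seed = 1L)
  base[names(args)] <- args
  do.call(sim_config, base)
}

# Build a trial table from per-participant perceived-time series.
# `spec` is a list of lists with fields id, group, AO, AS (numeric
# vectors of perceived times on 'at-12' trials), and optionally
# before/after (per condition, perceived times of non-'at' trials).
make_trials <- function(spec) {
  rows <- list()
  for (s in spec) {
    for (cond in c("AO", "AS")) {
      perc <- s[[cond]]
      n <- length(perc)
      extra_b <- s$before %||% numeric(0)
      extra_a <- s$after %||% numeric(0)
      all_perc <- c(perc, extra_b, extra_a)
      resp <- c(rep("at", n), rep("before", length(extra_b)),
                rep("after", length(extra_a)))
      nt <- length(all_perc)
      t2 <- 1800 * seq_len(nt) + 18000
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant_id = s$id, order_group = s$group, condition = cond,
        trial_index = seq_len(nt),
        at12_index = c(seq_len(n), rep(NA_integer_, nt - n)),
        t_press_ms = t2 - all_perc, t_twelve_ms = t2, response = resp)
    }
  }
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two mirrored groups with identical binding patterns: the order-group
# contrast is exactly null on this fixture.
mirrored_trials <- function() {
  make_trials(list(
    list(id = "A1", group = "AO-AS", AO = c(0, 5, 10, 15), AS = c(20, 25, 30, 35)),
    list(id = "A2", group = "AO-AS", AO = c(2, 7, 12, 17), AS = c(26, 31, 36, 41)),
    list(id = "B1", group = "AS-AO", AO = c(0, 5, 10, 15), AS = c(20, 25, 30, 35)),
    list(id = "B2", group = "AS-AO", AO = c(2, 7, 12, 17), AS = c(26, 31, 36, 41))
  ))
}

# Wide one-row PDI sheet with uniform answers.
pdi_sheet <- function(id = "P1", endorsed = rep(1L, 21), rating = 5L) {
  out <- tibble::tibble(participant_id = id)
  for (j in 1:21) {
    e <- endorsed[j]
    out[[paste0("endorsed_", j)]] <- e
    out[[paste0("distress_", j)]] <- if (e == 1) rating else NA_integer_
    out[[paste0("preoccupation_", j)]] <- if (e == 1) rating else NA_integer_
    out[[paste0("conviction_", j)]] <- if (e == 1) rating else NA_integer_
  }
  out
}
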