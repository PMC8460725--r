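test_that("the least-squares slope matches hand computation and lm", {
  fit <- trial_slope(c(2, 4, 6), c(1, 2, 3))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0)
  expect_equal(trial_slope(rep(5, 4))$slope, 0)
  expect_equal(trial_slope(c(2, 4, 6), c(3, 2, 1))$slope, -2)
  withr::with_seed(9, {
    y <- rnorm(25)
    x <- sample(1:40, 25)
    ref <- unname(coef(lm(y ~ x)))
    fit <- trial_slope(y, x)
    expect_equal(fit$intercept, ref[1], tolerance = 1e-10)
    expect_equal(fit$slope, ref[2], tolerance = 1e-10)
  })
  expect_error(trial_slope(c(1, 2), c(3, 3)), "constant predictor")
  expect_error(trial_slope(1), "at least 2")
})

test_that("carryover into the baseline condition shows up as signed AO slopes", {
  ao_slopes <- function(cfg_args, seeds) {
    sapply(seeds, function(s) {
      co <- simulate_cohort(do.call(sim_config,
                                    c(list(seed = s, n_per_group = 13),
                                      cfg_args)))
      sl <- condition_slopes(build_summaries(co$trials))
      c(ao_first = mean(sl$slope[sl$condition == "AO" &
                                   sl$order_group == "AO-AS"]),
        as_first = mean(sl$slope[sl$condition == "AO" &
                                   sl$order_group == "AS-AO"]))
    })
  }
  seeds <- withr::with_seed(314, sample.int(1e6, 40))
  # drift off: AO tested second starts from the AS shift and relaxes
  # downward, AO tested first is flat
  pure <- ao_slopes(list(drift_slope = 0), seeds)
  expect_lt(mean(pure["as_first", ]), 0)
  expect_lt(mean(pure["as_first", ]), mean(pure["ao_first", ]))
  # with the slow positive drift on, AO tested first develops upward
  drifted <- ao_slopes(list(), seeds)
  expect_gt(mean(drifted["ao_first", ]), 0)
  expect_lt(mean(drifted["as_first", ]), mean(drifted["ao_first", ]))
})

test_that("slope group tests report one-sample and between-group contrasts", {
  co <- simulate_cohort(sim_config(seed = 6))
  sl <- condition_slopes(build_summaries(co$trials))
  st <- slope_group_tests(sl)
  expect_equal(nrow(st$one_sample), 4)
  expect_equal(nrow(st$between_groups), 2)
  ao <- st$between_groups[st$between_groups$condition == "AO", ]
  expect_equal(ao$ds, cohen_ds(ao$t, 26, 26))
  expect_gt(ao$t, 0)  # AO-first slopes exceed AS-first slopes under carryover
})

test_that("the scan's first row equals the unscanned order contrast", {
  co <- simulate_cohort(sim_config(seed = 41))
  sm <- build_summaries(co$trials)
  rep <- cohort_binding_report(sm, n_drop = 0)
  scan <- leave_first_n_scan(sm, n_max = 5, participants = rep$kept)
  row0 <- scan$table[scan$table$n_dropped == 0, ]
  expect_equal(row0$t, rep$order_contrast$t)
  expect_equal(row0$p, rep$order_contrast$p)
  expect_equal(row0$mean_ao_first, rep$order_contrast$mean_ao_first)
})

test_that("identical groups scan to an exactly null contrast at every n", {
  scan <- leave_first_n_scan(build_summaries(mirrored_trials()), n_max = 2)
  expect_equal(scan$table$gap, rep(0, 3))
  # both groups have identical values, so the pooled variance is positive
  expect_equal(scan$table$t, rep(0, 3))
})

test_that("an infeasible n_max truncates the scan and records why", {
  sm <- build_summaries(mirrored_trials())
  scan <- leave_first_n_scan(sm, n_max = 10)
  expect_equal(max(scan$table$n_dropped), 3)
  expect_equal(scan$stopped_at, 4)
  expect_match(scan$stop_reason, "4 'at-12' trials")
})

test_that("the cutoff is the first n from which the scan stays non-significant", {
  fake_scan <- function(p) {
    structure(list(table = tibble::tibble(n_dropped = seq_along(p) - 1, p = p)),
              class = "clockbind_scan")
  }
  expect_equal(cutoff_from_scan(fake_scan(c(0.01, 0.03, 0.2, 0.3, 0.4, 0.6))), 2)
  expect_equal(cutoff_from_scan(fake_scan(rep(0.5, 6))), 0)
  expect_equal(cutoff_from_scan(fake_scan(c(0.2, 0.2, 0.2, 0.2, 0.2, 0.04,
                                            0.3, 0.3))), 6)
  expect_true(is.na(cutoff_from_scan(fake_scan(c(0.5, 0.5, 0.01)))))
  expect_equal(cutoff_from_scan(fake_scan(c(0.01, 0.3, 0.3, 0.01, 0.5)),
                                horizon = 2), 1)
  expect_error(cutoff_from_scan(fake_scan(c(0.5)), horizon = 3), "horizon")
})

test_that("longer carryover time constants push the cutoff later", {
  # the scanned group gap decays with the carryover, so the tau contrast
  # must be on the scale of the remaining-window midpoint to be visible
  seeds <- withr::with_seed(2718, sample.int(1e6, 12))
  cut_for_tau <- function(tau) {
    mean(sapply(seeds, function(s) {
      co <- simulate_cohort(sim_config(seed = s, carryover_tau = tau,
                                       binding_mean = 40, binding_sd = 5,
                                       aim_sd = 45))
      sm <- build_summaries(co$trials)
      scan <- leave_first_n_scan(sm, n_max = 25)
      n <- cutoff_from_scan(scan, alpha = 0.05)
      if (is.na(n)) 26 else n
    }))
  }
  expect_lt(cut_for_tau(6), cut_for_tau(20))
})
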