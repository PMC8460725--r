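test_that("config validation rejects impossible settings", {
  expect_error(sim_config(aim_sd = -1), "SDs")
  expect_error(sim_config(carryover_into_ao = 1.5), "carryover weights")
  expect_error(sim_config(pdi_binding_rho = 1.2), "pdi_binding_rho")
  expect_error(sim_config(trials_at12_target = 0), "trials_at12_target")
  expect_error(sim_config(response_threshold = 0), "response_threshold")
  expect_error(sim_config(pdi_binding_rho = 0.3, binding_sd = 0),
               "constant binding increment")
})

test_that("noise-free cohort is the identity case", {
  cfg <- noise_free_config(binding_mean = 0, baseline_shift_mean = 12,
                           n_per_group = 2)
  co <- simulate_cohort(cfg)
  expect_true(all(co$trials$response == "at"))
  perc <- perceived_keypress_time(co$trials$t_press_ms, co$trials$t_twelve_ms)
  expect_equal(perc, rep(12, nrow(co$trials)))
  est <- binding_estimates(build_summaries(co$trials), n_drop = 0)
  expect_equal(est$binding_ms, rep(0, 4))
})

test_that("a deterministic binding increment shifts every AS median by exactly that amount", {
  cfg <- noise_free_config(binding_mean = 23, baseline_shift_sd = 25,
                           n_per_group = 3)
  co <- simulate_cohort(cfg)
  sm <- build_summaries(co$trials)
  for (nd in c(0, 5, 20)) {
    est <- binding_estimates(sm, n_drop = nd)
    expect_equal(est$binding_ms, rep(23, 6))
  }
})

test_that("the same configuration and seed reproduce the cohort exactly", {
  a <- simulate_cohort(sim_config(seed = 99, n_per_group = 4))
  b <- simulate_cohort(sim_config(seed = 99, n_per_group = 4))
  expect_identical(a$trials, b$trials)
  expect_identical(a$pdi, b$pdi)
  expect_equal(as.data.frame(a$truth), as.data.frame(b$truth))
  c <- simulate_cohort(sim_config(seed = 100, n_per_group = 4))
  expect_false(identical(a$trials$t_press_ms, c$trials$t_press_ms))
})

test_that("an unreachable at-12 window fails with the acquisition error", {
  cfg <- noise_free_config(aim_bias = 200, n_per_group = 1,
                           max_attempts_per_condition = 50)
  expect_error(simulate_cohort(cfg), "max_attempts")
})

test_that("timestamps put every 12 o'clock crossing on the 1800 ms grid near the press", {
  co <- simulate_cohort(sim_config(seed = 5, n_per_group = 3))
  expect_true(all(co$trials$t_twelve_ms %% 1800 == 0))
  expect_true(all(abs(co$trials$t_press_ms - co$trials$t_twelve_ms) < 900))
  expect_true(all(co$trials$at12_index[co$trials$response == "at"] >= 1))
})

test_that("item-wise PDI tables reproduce the target overall score", {
  co <- simulate_cohort(sim_config(seed = 11))
  sc <- pdi_overall_score(co$pdi)
  expect_true(all(sc$complete))
  expect_equal(sc$overall_score, co$truth$pdi_score)
  expect_true(all(sc$overall_score >= 0 & sc$overall_score <= 336))
  # ratings present iff endorsed
  for (j in c(1, 7, 21)) {
    e <- co$pdi[[paste0("endorsed_", j)]] == 1
    expect_identical(!is.na(co$pdi[[paste0("distress_", j)]]), e)
    expect_identical(!is.na(co$pdi[[paste0("conviction_", j)]]), e)
  }
})

test_that("PDI scores are right-skewed and correlate with the binding increment", {
  skew <- replicate(20, {
    co <- simulate_cohort(sim_config(seed = sample.int(1e6, 1)))
    s <- co$truth$pdi_score
    (mean(s) - median(s)) / sd(s)
  })
  expect_gt(mean(skew), 0)
  withr::with_seed(42, {
    r <- replicate(80, {
      co <- simulate_cohort(sim_config(seed = sample.int(1e6, 1)))
      cor(co$truth$d, co$truth$pdi_score)
    })
  })
  expect_lt(abs(mean(r) - 0.27), 0.15)
  expect_gt(mean(r), 0)
})

test_that("negative aim bias yields more 'before' than 'after' responses", {
  co <- simulate_cohort(sim_config(seed = 21))
  tab <- table(co$trials$response)
  expect_gt(tab[["before"]], tab[["after"]])
})

test_that("per-condition SD of at-12 perceived times lands in the calibrated band", {
  co <- simulate_cohort(sim_config(seed = 31))
  sm <- build_summaries(co$trials)
  sds <- tapply(sm$series$perceived,
                paste(sm$series$participant_id, sm$series$condition), sd)
  expect_true(mean(sds) > 30 && mean(sds) < 55)
})

test_that("contaminant participants produce extreme average perceived times", {
  co <- simulate_cohort(sim_config(seed = 8, outlier_fraction = 0.1))
  expect_equal(sum(co$truth$outlier), round(0.1 * 52))
  sm <- build_summaries(co$trials)
  excl <- mad_median_exclusions(sm)
  expect_true(all(co$truth$participant_id[co$truth$outlier] %in%
                    excl$participant_id[excl$flagged]))
})

test_that("written cohorts round-trip through the CSV readers", {
  co <- simulate_cohort(sim_config(seed = 13, n_per_group = 3))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  tr <- read_trials(file.path(dir, "trials.csv"))
  expect_equal(as.data.frame(tr), as.data.frame(co$trials))
  pdi <- read_pdi(file.path(dir, "pdi.csv"))
  expect_equal(pdi_overall_score(pdi)$overall_score,
               pdi_overall_score(co$pdi)$overall_score)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$participants$d, co$truth$d)
})
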