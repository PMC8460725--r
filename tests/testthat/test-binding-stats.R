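test_that("the MAD-median rule flags exactly the hand-computed outliers", {
  p <- c(0, 10, 20, 30, 1000)
  # median 20, MAD 10; |1000-20|*0.6745 = 661.01 > 30; |0-20|*0.6745 = 13.49
  expect_identical(mad_median_outliers(p), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(mad_median_outliers(p + 500), mad_median_outliers(p))
  expect_identical(mad_median_outliers(rep(7, 5)), rep(FALSE, 5))
  expect_error(mad_median_outliers(c(1, 2)), "at least 3")
  expect_warning(flags <- mad_median_outliers(c(0, 0, 0, 0, 1)),
                 "MAD-median is zero")
  expect_identical(flags, c(FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("effect-size formulas match their closed forms", {
  expect_equal(cohen_dz(5.68, 52), 5.68 / sqrt(52))
  expect_equal(cohen_dz(0, 10), 0)
  expect_equal(cohen_ds(1, 8, 8), sqrt(2 / 8))
  expect_equal(cohen_ds(2.36, 26, 13), cohen_ds(2.36, 13, 26))
  expect_error(cohen_dz(1, 0), ">= 1")
  expect_error(cohen_ds(1, 0, 5), ">= 1")
})

test_that("paired and unpaired t match hand computation and textbook symmetries", {
  # differences 1,2,3: mean 2, sd 1 -> t = 2/(1/sqrt(3))
  pt <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(pt$t, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(pt$df, 2)
  expect_equal(paired_t(c(1, 2, 3), c(2, 4, 6))$t, -pt$t)
  expect_error(paired_t(c(1, 2), c(1, 2)), "zero-variance")
  expect_error(paired_t(1:3, 1:4), "equal length")

  ut <- unpaired_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(ut$t, -3 / sqrt(2 / 3), tolerance = 1e-10)  # pooled sd 1
  expect_equal(ut$df, 4)
  expect_equal(unpaired_t(c(1, 2, 3) + 10, c(4, 5, 6) + 10)$t, ut$t)
  expect_equal(unpaired_t(c(1, 2, 2, 1), c(1, 2, 1, 2))$t, 0)
  expect_error(unpaired_t(c(1, 1), c(1, 1)), "zero pooled variance")
})

test_that("the internal pooled-t closed form agrees with the t.test route", {
  withr::with_seed(4, {
    for (i in 1:20) {
      x <- rnorm(sample(3:30, 1))
      y <- rnorm(sample(3:30, 1), mean = runif(1, -2, 2))
      expect_equal(clockbind:::student_t_stat(x, y),
                   unpaired_t(x, y)$t, tolerance = 1e-12)
    }
  })
})

test_that("binding estimates combine truncated medians and the trial-level t", {
  tr <- make_trials(list(
    list(id = "P1", group = "AO-AS", AO = c(0, 0, 0, 0), AS = c(10, 10, 20, 20))
  ))
  sm <- build_summaries(tr)
  est <- binding_estimates(sm, n_drop = 0)
  expect_equal(est$binding_ms, 15)
  expect_equal(est$binding_t,
               unpaired_t(c(10, 10, 20, 20), c(0, 0, 0, 0))$t)
  est2 <- binding_estimates(sm, n_drop = 2)
  expect_equal(est2$binding_ms, 20)
  expect_error(binding_estimates(sm, n_drop = 4), "insufficient")
})

test_that("binding_t and binding_ms agree in sign on symmetric series", {
  tr <- make_trials(list(
    list(id = "P1", group = "AO-AS", AO = c(-5, 0, 5), AS = c(15, 20, 25)),
    list(id = "P2", group = "AS-AO", AO = c(10, 20, 30), AS = c(-10, 0, 10))
  ))
  est <- binding_estimates(build_summaries(tr), n_drop = 0)
  expect_equal(sign(est$binding_t), sign(est$binding_ms))
})

test_that("the cohort report excludes MAD-median outliers before any statistic", {
  spec <- lapply(1:8, function(i) {
    list(id = sprintf("K%d", i),
         group = if (i <= 4) "AO-AS" else "AS-AO",
         AO = c(0, 2, 4, 6) + i, AS = c(20, 22, 24, 26) + 2 * i)
  })
  spec[[9]] <- list(id = "X1", group = "AO-AS",
                    AO = c(780, 782, 784, 786), AS = c(800, 802, 804, 806))
  rep <- cohort_binding_report(build_summaries(make_trials(spec)))
  expect_true(rep$exclusions$flagged[rep$exclusions$participant_id == "X1"])
  expect_false("X1" %in% rep$kept)
  expect_false("X1" %in% rep$estimates$participant_id)
  expect_equal(sum(rep$exclusions$flagged), 1)
  # per-participant binding is 20 + i on this fixture
  expect_equal(rep$paired$mean_binding[rep$paired$scope == "all"],
               20 + mean(1:8))
})

test_that("condition means carry t-based confidence intervals", {
  tr <- mirrored_trials()
  rep <- cohort_binding_report(build_summaries(tr))
  all_ao <- rep$condition_means[rep$condition_means$scope == "all" &
                                  rep$condition_means$condition == "AO", ]
  x <- c(7.5, 9.5, 7.5, 9.5)  # the four AO medians
  se <- sd(x) / sqrt(4)
  expect_equal(all_ao$mean, mean(x))
  expect_equal(all_ao$ci_high, mean(x) + qt(0.975, 3) * se, tolerance = 1e-10)
})

test_that("identical groups give an exactly null order contrast", {
  rep <- cohort_binding_report(build_summaries(mirrored_trials()))
  expect_equal(rep$order_contrast$t, 0)
  expect_equal(rep$order_contrast$p, 1)
  expect_equal(rep$order_contrast$mean_ao_first,
               rep$order_contrast$mean_as_first)

  # groups with no internal variance at all degenerate to NA, not to a
  # misleading zero
  flat <- make_trials(list(
    list(id = "F1", group = "AO-AS", AO = c(0, 0), AS = c(20, 20)),
    list(id = "F2", group = "AO-AS", AO = c(0, 0), AS = c(20, 20)),
    list(id = "F3", group = "AS-AO", AO = c(0, 0), AS = c(20, 20)),
    list(id = "F4", group = "AS-AO", AO = c(0, 0), AS = c(20, 20))
  ))
  rep2 <- cohort_binding_report(build_summaries(flat))
  expect_true(is.na(rep2$order_contrast$t))
})
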