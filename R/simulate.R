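#' Simulation configuration for a synthetic Libet-clock cohort
#'
#' Builds a validated configuration for [simulate_cohort()].  The defaults
#' describe a two-group cohort (testing order AO-AS vs AS-AO, 26
#' participants each) whose statistical structure mirrors a typical
#' action-binding experiment: per-participant subjective timing shifts,
#' a binding increment added in the action-sound (AS) condition,
#' exponentially decaying carryover from the previously tested condition,
#' and aiming/judgement noise that yields per-condition standard
#' deviations of the perceived keypress time near 41 ms.
#'
#' @param n_per_group participants per testing-order group.
#' @param baseline_shift_mean,baseline_shift_sd ms; mean and SD of the
#'   per-participant baseline (AO) subjective shift `b_i`.
#' @param binding_mean,binding_sd ms; mean and SD of the per-participant
#'   binding increment `d_i` added in the AS condition.
#' @param carryover_tau e-folding constant of the carryover decay, in
#'   units of acquired 'at-12' trials.
#' @param carryover_into_ao,carryover_into_as carryover weights in
#'   `[0, 1]`: how strongly the AO (resp. AS) condition, when tested
#'   second, starts from the asymptotic shift of the condition tested
#'   first.  The asymmetric defaults (1, 0) encode carryover that acts
#'   mainly on the baseline condition.
#' @param drift_slope ms per acquired 'at-12' trial; slow drift common to
#'   both conditions.
#' @param aim_sd,aim_bias ms; SD and mean of the aiming/judgement error
#'   `eta`.  A negative bias makes early presses (and 'before 12'
#'   responses) more common than late ones.
#' @param response_threshold ms; half-width of the subjective 'at 12'
#'   window applied to `eta`.
#' @param trials_at12_target number of 'at-12' trials acquired per
#'   condition before it ends.
#' @param max_attempts_per_condition hard cap on emitted trials per
#'   condition; exceeding it signals that `response_threshold` is too
#'   small relative to `aim_sd`.
#' @param pdi_binding_rho target Pearson correlation between the latent
#'   delusional trait and the measured per-participant binding strength
#'   (the trial-level t statistic computed from trials 11..end per
#'   condition).  The generator inverts the known attenuation of that
#'   estimator to choose the latent trait/binding-increment correlation;
#'   see [attenuation_factors()].
#' @param pdi_shape length-2 positive vector; Beta shape parameters of
#'   the monotone right-skewed map from the latent trait to the PDI-21
#'   overall score on `[0, 336]`.
#' @param outlier_fraction fraction of contaminant participants whose
#'   baseline shift is displaced by ±250 ms (exercises the MAD-median
#'   exclusion rule).
#' @param seed integer seed; all randomness in [simulate_cohort()] flows
#'   from it.
#'
#' @return A list of class `clockbind_sim_config`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_per_group = 26,
                       baseline_shift_mean = 15,
                       baseline_shift_sd = 25,
                       binding_mean = 23,
                       binding_sd = 15,
                       carryover_tau = 3,
                       carryover_into_ao = 1,
                       carryover_into_as = 0,
                       drift_slope = 0.3,
                       aim_sd = 60,
                       aim_bias = -10,
                       response_threshold = 80,
                       trials_at12_target = 40,
                       max_attempts_per_condition = 400,
                       pdi_binding_rho = 0.27,
                       pdi_shape = c(1.2, 6),
                       outlier_fraction = 0,
                       seed = 1L) {
  cfg <- list(
    n_per_group = as.integer(n_per_group),
    baseline_shift_mean = baseline_shift_mean,
    baseline_shift_sd = baseline_shift_sd,
    binding_mean = binding_mean,
    binding_sd = binding_sd,
    carryover_tau = carryover_tau,
    carryover_into_ao = carryover_into_ao,
    carryover_into_as = carryover_into_as,
    drift_slope = drift_slope,
    aim_sd = aim_sd,
    aim_bias = aim_bias,
    response_threshold = response_threshold,
    trials_at12_target = as.integer(trials_at12_target),
    max_attempts_per_condition = as.integer(max_attempts_per_condition),
    pdi_binding_rho = pdi_binding_rho,
    pdi_shape = pdi_shape,
    outlier_fraction = outlier_fraction,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "clockbind_sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    "n_per_group must be >= 1" = cfg$n_per_group >= 1L,
    "SDs must be >= 0" = cfg$baseline_shift_sd >= 0 && cfg$binding_sd >= 0 &&
      cfg$aim_sd >= 0,
    "carryover_tau must be > 0" = cfg$carryover_tau > 0,
    "carryover weights must lie in [0, 1]" =
      cfg$carryover_into_ao >= 0 && cfg$carryover_into_ao <= 1 &&
      cfg$carryover_into_as >= 0 && cfg$carryover_into_as <= 1,
    "response_threshold must be > 0" = cfg$response_threshold > 0,
    "trials_at12_target must be >= 1" = cfg$trials_at12_target >= 1L,
    "max_attempts_per_condition must cover the target" =
      cfg$max_attempts_per_condition >= cfg$trials_at12_target,
    "|pdi_binding_rho| must be <= 1" = abs(cfg$pdi_binding_rho) <= 1,
    "pdi_shape must be two positive numbers" =
      length(cfg$pdi_shape) == 2L && all(cfg$pdi_shape > 0),
    "outlier_fraction must lie in [0, 1]" =
      cfg$outlier_fraction >= 0 && cfg$outlier_fraction <= 1,
    "seed must be a finite integer" = is.finite(cfg$seed)
  )
  if (cfg$pdi_binding_rho != 0 && cfg$binding_sd == 0) {
    stop("pdi_binding_rho != 0 requires binding_sd > 0 ",
         "(a constant binding increment cannot carry a correlation)")
  }
  invisible(cfg)
}

#' Moments of the aiming error retained on 'at-12' trials
#'
#' Mean and SD of `eta ~ Normal(aim_bias, aim_sd^2)` conditional on
#' `|eta| <= response_threshold`, i.e. of the judgement noise surviving
#' the 'at 12' response filter (standard truncated-normal moments).
#'
#' @param cfg a `clockbind_sim_config`.
#' @return list with `mean`, `sd` and `p_at` (probability of an 'at 12'
#'   response).
#' @keywords internal
truncated_aim_moments <- function(cfg) {
  mu <- cfg$aim_bias
  sigma <- cfg$aim_sd
  theta <- cfg$response_threshold
  if (sigma == 0) {
    inside <- abs(mu) <= theta
    return(list(mean = if (inside) mu else NA_real_,
                sd = 0, p_at = as.numeric(inside)))
  }
  a <- (-theta - mu) / sigma
  b <- (theta - mu) / sigma
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  list(mean = m, sd = sqrt(max(v, 0)), p_at = z)
}

#' Attenuation of the trait-binding correlation under the standard estimator
#'
#' The observable correlation between a participant trait and the measured
#' binding strength is smaller than the latent trait/binding-increment
#' correlation for two reasons: (i) the binding strength is estimated from
#' a finite number of noisy trials, and (ii) the PDI overall score is a
#' nonlinear (right-skewed) monotone transform of the latent trait.  This
#' helper returns both shrinkage factors so the generator can invert them.
#'
#' `measurement` is `binding_sd / sqrt(binding_sd^2 + 2 * sigma_at^2 / m)`
#' where `sigma_at` is the truncated aiming-noise SD and `m` the number of
#' trials per condition entering the default binding-strength estimator
#' (trials 11..end, the convention used downstream).  `score` is the
#' Pearson correlation between a standard normal trait and its Beta-quantile
#' score transform, computed by numerical integration.
#'
#' @param cfg a `clockbind_sim_config`.
#' @return list with `measurement`, `score`, and their product `total`.
#' @export
attenuation_factors <- function(cfg) {
  m <- max(cfg$trials_at12_target - 10L, 2L)
  sig <- truncated_aim_moments(cfg)$sd
  meas <- if (cfg$binding_sd == 0) {
    1
  } else {
    cfg$binding_sd / sqrt(cfg$binding_sd^2 + 2 * sig^2 / m)
  }
  a <- cfg$pdi_shape[1]
  b <- cfg$pdi_shape[2]
  f <- function(z) stats::qbeta(stats::pnorm(z), a, b)
  ez <- stats::integrate(function(z) f(z) * stats::dnorm(z), -8, 8)$value
  ezf <- stats::integrate(function(z) z * f(z) * stats::dnorm(z), -8, 8)$value
  ef2 <- stats::integrate(function(z) f(z)^2 * stats::dnorm(z), -8, 8)$value
  score <- (ezf - 0 * ez) / sqrt(ef2 - ez^2)
  list(measurement = meas, score = score, total = meas * score)
}

latent_trait_correlation <- function(cfg) {
  if (cfg$pdi_binding_rho == 0) return(0)
  att <- attenuation_factors(cfg)$total
  rho <- cfg$pdi_binding_rho / att
  if (abs(rho) > 0.99) {
    warning("target pdi_binding_rho not reachable after attenuation; ",
            "latent correlation capped at 0.99")
    rho <- sign(rho) * 0.99
  }
  rho
}

# One condition block for one participant.  `k` counts 'at-12' trials
# already acquired in this condition; carryover and drift are indexed by k,
# not by raw attempts, because the downstream analysis indexes 'at-12'
# trials only.
simulate_condition <- function(base, prev_end, weight, cfg, t_origin) {
  target <- cfg$trials_at12_target
  theta <- cfg$response_threshold
  eta <- numeric(0)
  repeat {
    need <- max(64L, 2L * target)
    eta <- c(eta, stats::rnorm(need, cfg$aim_bias, cfg$aim_sd))
    at <- abs(eta) <= theta
    if (sum(at) >= target || length(eta) >= cfg$max_attempts_per_condition) break
  }
  at <- abs(eta) <= theta
  hit <- which(cumsum(at) == target & at)
  if (length(hit) == 0 || hit[1] > cfg$max_attempts_per_condition) {
    stop("max_attempts_per_condition exceeded before acquiring ",
         target, " 'at-12' trials; response_threshold is too small ",
         "relative to aim_sd")
  }
  n_t <- hit[1]
  eta <- eta[seq_len(n_t)]
  at <- at[seq_len(n_t)]
  k <- cumsum(at) - at                    # acquired count before this trial
  carry <- if (is.na(prev_end)) 0 else weight * (prev_end - base) *
    exp(-k / cfg$carryover_tau)
  s <- base + carry + cfg$drift_slope * k
  a <- -s + eta                           # actual press re the crossing
  # timestamps: crossings on an 1800 ms grid, >= 2 s inter-trial period
  iti <- stats::runif(n_t, 2000, 2500)
  cursor <- t_origin + cumsum(iti + 3300)
  t2 <- 1800 * round(cursor / 1800)
  t1 <- t2 + a
  resp <- ifelse(eta < -theta, "before", ifelse(eta > theta, "after", "at"))
  at12_index <- rep(NA_integer_, n_t)
  at12_index[at] <- seq_len(sum(at))
  list(
    trial_index = seq_len(n_t),
    at12_index = at12_index,
    t_press_ms = t1,
    t_twelve_ms = t2,
    response = resp
  )
}

#' Simulate a synthetic action-binding cohort
#'
#' Generates a trial-level table, a PDI-21 questionnaire table, and a
#' ground-truth ledger for a cohort of participants performing the
#' modified Libet-clock task in both conditions (AO = action only,
#' AS = action + delayed sound), in counterbalanced testing order.
#'
#' Per trial, the subjective shift is
#' `s = b_i + d_i*[AS] + w*(s_prev - s_base)*exp(-k/tau) + drift*k`,
#' with `k` the number of 'at-12' trials already acquired in the current
#' condition and `s_prev` the asymptotic shift of the condition tested
#' first (carryover is zero in the first condition).  The aiming error
#' `eta` determines both the actual press time `a = -s + eta` (ms relative
#' to the 12 o'clock crossing) and the response category via the
#' subjective press position `q = a + s = eta` against the 'at-12' window.
#' Trials are emitted until `trials_at12_target` 'at-12' trials exist.
#'
#' The latent delusional trait `z_i` and the standardised binding
#' increment are bivariate normal; their correlation is chosen so that
#' the *measured* binding strength (trial-level t statistic) correlates
#' with the PDI overall score at `pdi_binding_rho` (see
#' [attenuation_factors()]).  The PDI overall score is a monotone
#' right-skewed Beta-quantile transform of `z_i`, realised item-wise.
#'
#' @param config a [sim_config()].
#' @return A list of class `clockbind_cohort` with elements
#'   * `trials`: tibble with columns `participant_id`, `order_group`
#'     (`AO-AS`/`AS-AO`), `condition` (`AO`/`AS`), `trial_index`,
#'     `at12_index` (NA unless the response was 'at'), `t_press_ms`,
#'     `t_twelve_ms`, `response` (`before`/`at`/`after`);
#'   * `pdi`: tibble with `participant_id` and, per item i in 1..21,
#'     `endorsed_i` plus `distress_i`, `preoccupation_i`, `conviction_i`
#'     (NA when not endorsed);
#'   * `truth`: tibble with per-participant `b` (baseline shift, ms),
#'     `d` (binding increment, ms), `z` (latent trait), `pdi_score`,
#'     `outlier`; the config and the latent correlation actually used are
#'     attached as attributes `config` and `rho_latent`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- 2L * cfg$n_per_group
  id <- sprintf("P%03d", seq_len(n))
  grp <- rep(c("AO-AS", "AS-AO"), each = cfg$n_per_group)

  rho_z <- latent_trait_correlation(cfg)
  z <- stats::rnorm(n)
  zeta <- rho_z * z + sqrt(1 - rho_z^2) * stats::rnorm(n)
  d <- cfg$binding_mean + cfg$binding_sd * zeta
  b <- stats::rnorm(n, cfg$baseline_shift_mean, cfg$baseline_shift_sd)

  n_out <- round(cfg$outlier_fraction * n)
  outlier <- rep(FALSE, n)
  if (n_out > 0) {
    idx <- sample.int(n, n_out)
    outlier[idx] <- TRUE
    b[idx] <- b[idx] + sample(c(-250, 250), n_out, replace = TRUE)
  }

  sub_seed <- sample.int(.Machine$integer.max - 1L, n)
  parts <- vector("list", n)
  for (i in seq_len(n)) {
    first <- if (grp[i] == "AO-AS") "AO" else "AS"
    second <- if (first == "AO") "AS" else "AO"
    base_of <- function(cond) b[i] + d[i] * (cond == "AS")
    w2 <- if (second == "AO") cfg$carryover_into_ao else cfg$carryover_into_as
    parts[[i]] <- withr::with_seed(sub_seed[i], {
      c1 <- simulate_condition(base_of(first), NA_real_, 0, cfg, 0)
      c2 <- simulate_condition(base_of(second), base_of(first), w2, cfg,
                               max(c1$t_press_ms) + 60000)
      k1 <- length(c1$trial_index)
      k2 <- length(c2$trial_index)
      list(participant_id = rep(id[i], k1 + k2),
           order_group = rep(grp[i], k1 + k2),
           condition = c(rep(first, k1), rep(second, k2)),
           trial_index = c(c1$trial_index, c2$trial_index),
           at12_index = c(c1$at12_index, c2$at12_index),
           t_press_ms = c(c1$t_press_ms, c2$t_press_ms),
           t_twelve_ms = c(c1$t_twelve_ms, c2$t_twelve_ms),
           response = c(c1$response, c2$response))
    })
  }
  trials <- tibble::as_tibble(lapply(stats::setNames(nm = names(parts[[1]])),
                                     function(col) {
                                       unlist(lapply(parts, `[[`, col),
                                              use.names = FALSE)
                                     }))

  pdi_score <- pdi_score_from_trait(z, cfg$pdi_shape)
  pdi <- simulate_pdi_items(id, pdi_score)

  truth <- tibble::tibble(participant_id = id, order_group = grp,
                          b = b, d = d, z = z,
                          pdi_score = pdi_score, outlier = outlier)
  attr(truth, "config") <- unclass(cfg)
  attr(truth, "rho_latent") <- rho_z

  structure(list(trials = trials, pdi = pdi, truth = truth),
            class = "clockbind_cohort")
}

# Monotone right-skewed map from a standard-normal trait to the PDI-21
# overall score on [0, 336].  Scores 1..3 are unreachable item-wise (the
# smallest endorsed item contributes 4 points) and snap up to 4.
pdi_score_from_trait <- function(z, shape) {
  s <- round(336 * stats::qbeta(stats::pnorm(z), shape[1], shape[2]))
  s[s >= 1 & s <= 3] <- 4
  as.integer(s)
}

# Item-wise realisation of a target overall score: endorse the fewest
# items that can carry the score, then scatter the remaining points
# uniformly over the (item x rating) capacity.  Any allocation consistent
# with the overall score is statistically equivalent downstream.
simulate_pdi_items <- function(id, score) {
  n <- length(id)
  endorsed <- matrix(0L, n, 21)
  rate <- array(NA_integer_, c(n, 21, 3))
  for (i in seq_len(n)) {
    s <- score[i]
    if (s == 0) next
    n_end <- max(1L, ceiling(s / 16))
    items <- sort(sample.int(21L, n_end))
    endorsed[i, items] <- 1L
    extra <- s - 4L * n_end            # each endorsed item starts at 1+1+1+1
    stopifnot(extra >= 0, extra <= 12L * n_end)
    slot <- integer(12L * n_end)       # 3 rating dims x 4 spare points each
    if (extra > 0) slot[sample.int(length(slot), extra)] <- 1L
    add <- matrix(colSums(matrix(slot, nrow = 4)), nrow = 3) # 3 x n_end
    for (jj in seq_along(items)) {
      rate[i, items[jj], ] <- 1L + add[, jj]
    }
  }
  out <- tibble::tibble(participant_id = id)
  for (j in 1:21) {
    out[[paste0("endorsed_", j)]] <- endorsed[, j]
    out[[paste0("distress_", j)]] <- rate[, j, 1]
    out[[paste0("preoccupation_", j)]] <- rate[, j, 2]
    out[[paste0("conviction_", j)]] <- rate[, j, 3]
  }
  out
}

#' Write a simulated cohort to disk
#'
#' Writes `trials.csv`, `pdi.csv` and `truth.json` (ground truth plus the
#' generating configuration) into `dir`.
#'
#' @param cohort a `clockbind_cohort` from [simulate_cohort()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "clockbind_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$pdi, file.path(dir, "pdi.csv"),
                   row.names = FALSE, na = "")
  truth <- list(
    config = attr(cohort$truth, "config"),
    rho_latent = attr(cohort$truth, "rho_latent"),
    participants = as.data.frame(cohort$truth)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
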