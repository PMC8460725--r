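#' Run the full action-binding analysis
#'
#' Orchestrates the four analysis stages on a trial table (and optional
#' PDI table): (1) validity of the before/at/after judgement,
#' (2) MAD-median exclusion and the group binding report, (3) the
#' trial-by-trial slope tests plus the leave-first-n-out order-effect
#' scan with its cutoff, and (4) the delusional-ideation correlation on
#' the binding strength computed with `n_drop` leading trials removed.
#'
#' @param trials validated trial table (see [read_trials()]).
#' @param pdi optional PDI table; `NULL` skips the correlation stage.
#' @param n_drop leading 'at-12' trials dropped per condition for the
#'   binding-strength estimates (default 10).
#' @param alpha significance level for the scan cutoff.
#' @param n_max,horizon scan range and stability horizon (see
#'   [leave_first_n_scan()] and [cutoff_from_scan()]).
#' @param n_boot,seed bootstrap settings for the correlation stage.
#' @param out_dir optional directory; when given, the bundle is written
#'   as JSON/CSV artifacts that embed the package version, seed and
#'   settings.
#' @return list of class `clockbind_bundle` with elements `validity`,
#'   `binding`, `slopes`, `slope_tests`, `scan`, `cutoff`,
#'   `correlation` (possibly `NULL`), and `settings`.
#' @export
run_pipeline <- function(trials, pdi = NULL, n_drop = 10, alpha = 0.05,
                         n_max = 30, horizon = NULL, n_boot = 2000,
                         seed = 1L, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  trials <- stage("input", validate_trials(trials))
  summaries <- stage("prepare", build_summaries(trials))
  validity <- stage("validity", response_validity_report(trials))
  binding <- stage("binding", cohort_binding_report(summaries, n_drop = 0))
  kept <- binding$kept
  slopes <- stage("slopes", condition_slopes(summaries, participants = kept))
  slope_tests <- stage("slopes", slope_group_tests(slopes))
  scan <- stage("scan",
                leave_first_n_scan(summaries, n_max = n_max,
                                   participants = kept))
  cutoff <- stage("scan", cutoff_from_scan(scan, alpha = alpha,
                                           horizon = horizon))
  correlation <- NULL
  if (!is.null(pdi)) {
    est <- stage("correlate",
                 binding_estimates(summaries, n_drop = n_drop,
                                   participants = kept))
    correlation <- stage("correlate",
                         delusion_binding_analysis(est, pdi,
                                                   n_boot = n_boot,
                                                   seed = seed))
  }
  settings <- list(package_version = as.character(utils::packageVersion("clockbind")),
                   n_drop = n_drop, alpha = alpha, n_max = n_max,
                   horizon = horizon, n_boot = n_boot, seed = as.integer(seed))
  bundle <- structure(list(validity = validity, binding = binding,
                           slopes = slopes, slope_tests = slope_tests,
                           scan = scan, cutoff = cutoff,
                           correlation = correlation, settings = settings),
                      class = "clockbind_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

de_tibble <- function(x) {
  if (inherits(x, "data.frame")) return(as.data.frame(x))
  if (is.list(x)) return(lapply(x, de_tibble))
  x
}

#' Write an analysis bundle to disk
#'
#' Writes `report.json` (everything except the scan table), and
#' `scan.csv` (one row per number of dropped trials).
#'
#' @param bundle a `clockbind_bundle`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "clockbind_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$scan$table, file.path(dir, "scan.csv"),
                   row.names = FALSE)
  report <- de_tibble(lapply(unclass(bundle), function(x) {
    if (inherits(x, "clockbind_scan")) x$table <- NULL
    if (inherits(x, c("clockbind_validity", "clockbind_binding_report",
                      "clockbind_scan", "clockbind_delusion_result",
                      "clockbind_correlation"))) unclass(x) else x
  }))
  report$correlation$correlation <- unclass(report$correlation$correlation)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  invisible(dir)
}

#' @export
print.clockbind_bundle <- function(x, ...) {
  cat("Action-binding analysis bundle\n")
  cm <- x$binding$condition_means
  all_m <- cm[cm$scope == "all", ]
  for (i in seq_len(nrow(all_m))) {
    cat(sprintf("  %s condition: mean perceived keypress time %.2f ms (95%% CI [%.2f %.2f], n = %d)\n",
                all_m$condition[i], all_m$mean[i], all_m$ci_low[i],
                all_m$ci_high[i], all_m$n[i]))
  }
  pa <- x$binding$paired[x$binding$paired$scope == "all", ]
  if (nrow(pa)) {
    cat(sprintf("  action binding (AS - AO): %.2f ms, t(%d) = %.2f, p = %.3g, one-tailed, dz = %.2f\n",
                pa$mean_binding, pa$df, pa$t, pa$p, pa$dz))
  }
  oc <- x$binding$order_contrast
  if (!is.null(oc)) {
    cat(sprintf("  order-group contrast on binding: t(%d) = %.2f, p = %.3g, two-tailed, ds = %.2f\n",
                oc$df, oc$t, oc$p, oc$ds))
  }
  cat(sprintf("  excluded by MAD-median rule: %d of %d\n",
              sum(x$binding$exclusions$flagged),
              nrow(x$binding$exclusions)))
  if (!is.na(x$cutoff)) {
    cat(sprintf("  order effect non-significant from %d dropped trials on (alpha = %.2f)\n",
                x$cutoff, x$settings$alpha))
  }
  if (!is.null(x$correlation)) {
    co <- x$correlation$correlation
    le <- x$correlation$ledger
    cat(sprintf("  PDI vs binding strength: r = %.2f, p = %.3g, one-tailed, 95%% CI [%.2f %.2f], n = %d (%d - %d incomplete - %d boxplot)\n",
                co$r, co$p, co$ci_low, co$ci_high, le$n_used, le$n_in,
                le$n_incomplete, le$n_boxplot))
  }
  invisible(x)
}
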