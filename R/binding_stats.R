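#' MAD-median participant exclusion rule
#'
#' Flags value `p` as an outlier when
#' `|p - median(P)| * 0.6745 > 3 * MAD` where `MAD` is the median
#' absolute deviation from the median of the full vector `P`
#' (candidates included).  The 0.6745 factor rescales the comparison to
#' standard-deviation units for normal data, so the rule is roughly a
#' robust 4.45-sigma cut.
#'
#' When MAD is exactly zero but the values are not all identical (more
#' than half the values tie at the median), every value unequal to the
#' median is flagged and a warning is emitted, since the printed
#' inequality would otherwise flag any deviation of measure zero.
#'
#' @param values numeric vector (length >= 3).
#' @return logical vector of flags, same length as `values`.
#' @export
mad_median_outliers <- function(values) {
  if (length(values) < 3) stop("need at least 3 values")
  if (anyNA(values)) stop("missing values")
  med <- stats::median(values)
  mad <- stats::median(abs(values - med))
  if (mad == 0) {
    if (all(values == med)) return(rep(FALSE, length(values)))
    warning("MAD-median is zero with non-identical values; ",
            "flagging all values unequal to the median")
    return(values != med)
  }
  abs(values - med) * 0.6745 > 3 * mad
}

#' Cohen's effect sizes from t statistics
#'
#' For a paired design, `dz = t / sqrt(n)`; for an unpaired two-group
#' design, `ds = t * sqrt(1/n1 + 1/n2)`.
#'
#' @param t t statistic.
#' @param n,n1,n2 sample sizes (pairs; group sizes).
#' @return effect size (numeric).
#' @export
cohen_dz <- function(t, n) {
  if (any(n < 1)) stop("n must be >= 1")
  t / sqrt(n)
}

#' @rdname cohen_dz
#' @export
cohen_ds <- function(t, n1, n2) {
  if (any(n1 < 1) || any(n2 < 1)) stop("group sizes must be >= 1")
  t * sqrt(1 / n1 + 1 / n2)
}

tail_alternative <- function(tail) {
  switch(tail,
         two = "two.sided", greater = "greater", less = "less",
         stop("tail must be 'two', 'greater' or 'less'"))
}

#' Paired and unpaired t tests
#'
#' Thin wrappers around [stats::t.test()] returning `(t, df, p)`.
#' `paired_t(x, y)` tests the mean of `x - y`; `unpaired_t(x, y)` is the
#' Student (pooled-variance) two-sample test, the design-appropriate form
#' here because group/trial counts are equal by design and the `ds`
#' effect-size formula is the pooled one.  Degenerate inputs (zero
#' variance) are rejected with an explicit error rather than returning a
#' misleading t = 0 or Inf.
#'
#' @param x,y numeric vectors (paired: equal length >= 2; unpaired: each
#'   length >= 2).
#' @param tail `"two"`, `"greater"` (x > y) or `"less"`.
#' @param var_equal use the pooled-variance Student test (default); set
#'   `FALSE` for Welch.
#' @return list with `t`, `df`, `p`.
#' @export
paired_t <- function(x, y, tail = "two") {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0) stop("zero-variance differences")
  ht <- stats::t.test(d, alternative = tail_alternative(tail))
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' @rdname paired_t
#' @export
unpaired_t <- function(x, y, tail = "two", var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 values per group")
  if (stats::sd(c(x - mean(x), y - mean(y))) == 0) {
    stop("zero pooled variance")
  }
  ht <- stats::t.test(x, y, alternative = tail_alternative(tail),
                      var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Per-participant binding estimates
#'
#' The action-binding effect per participant is summarised two ways on
#' the 'at-12' series truncated to trials `n_drop + 1 .. end` of each
#' condition: `binding_ms`, the AS median minus the AO median of the
#' perceived keypress time; and `binding_t`, the trial-level unpaired
#' Student t statistic of AS vs AO perceived times, which additionally
#' weights the participant's measurement precision and is the
#' "binding strength" used in the trait correlation.  Dropping the first
#' trials of each condition mitigates the testing-order carryover.
#'
#' @param summaries a `clockbind_summaries` from [build_summaries()].
#' @param n_drop number of leading 'at-12' trials to drop per condition
#'   (default 10).
#' @param participants optional character vector restricting the
#'   participants (e.g. after exclusion).
#' @return tibble with `participant_id`, `order_group`, `binding_ms`,
#'   `binding_t`, `n_drop`, `n_ao`, `n_as`.
#' @export
binding_estimates <- function(summaries, n_drop = 10, participants = NULL) {
  stopifnot(inherits(summaries, "clockbind_summaries"), n_drop >= 0)
  series <- summaries$series
  if (!is.null(participants)) {
    series <- dplyr::filter(series, .data$participant_id %in% participants)
  }
  short <- series |>
    dplyr::count(.data$participant_id, .data$condition) |>
    dplyr::filter(.data$n <= n_drop)
  if (nrow(short) > 0) {
    stop("insufficient 'at-12' trials after dropping ", n_drop,
         " for: ", paste(unique(short$participant_id), collapse = ", "))
  }
  keep <- series$at12_index > n_drop
  pid <- series$participant_id[keep]
  cond <- series$condition[keep]
  perc <- series$perceived[keep]
  ids <- unique(pid)
  grp <- series$order_group[keep][match(ids, pid)]
  ao_l <- split(perc[cond == "AO"],
                factor(pid[cond == "AO"], levels = ids))
  as_l <- split(perc[cond == "AS"],
                factor(pid[cond == "AS"], levels = ids))
  out <- lapply(seq_along(ids), function(i) {
    ao <- ao_l[[i]]
    as_ <- as_l[[i]]
    bt <- if (length(ao) >= 2 && length(as_) >= 2) {
      student_t_stat(as_, ao)
    } else {
      NA_real_
    }
    c(binding_ms = median_fast(as_) - median_fast(ao), binding_t = bt,
      n_ao = length(ao), n_as = length(as_))
  })
  out <- do.call(rbind, out)
  tibble::tibble(participant_id = ids, order_group = grp,
                 binding_ms = as.numeric(out[, "binding_ms"]),
                 binding_t = as.numeric(out[, "binding_t"]),
                 n_drop = n_drop,
                 n_ao = as.integer(out[, "n_ao"]),
                 n_as = as.integer(out[, "n_as"]))
}

# pooled-variance two-sample t statistic (x vs y), closed form; NA when
# the pooled variance vanishes.  Agrees with unpaired_t()$t -- asserted
# in the test suite -- but avoids htest overhead in per-participant loops.
student_t_stat <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 == 0) return(NA_real_)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

#' Participant exclusion by the MAD-median rule
#'
#' Applies [mad_median_outliers()] to the per-participant statistic the
#' exclusion is defined on: the average of the AO and AS medians of the
#' (untruncated) 'at-12' perceived keypress times.
#'
#' @param summaries a `clockbind_summaries`.
#' @return tibble `participant_id`, `order_group`, `p_stat` (ms),
#'   `flagged`, `rule`.
#' @export
mad_median_exclusions <- function(summaries) {
  stopifnot(inherits(summaries, "clockbind_summaries"))
  stat <- summaries$medians |>
    tidyr::pivot_wider(names_from = "condition", values_from = "median",
                       id_cols = c("participant_id", "order_group")) |>
    dplyr::mutate(p_stat = (.data$AO + .data$AS) / 2)
  tibble::tibble(participant_id = stat$participant_id,
                 order_group = stat$order_group,
                 p_stat = stat$p_stat,
                 flagged = mad_median_outliers(stat$p_stat),
                 rule = "mad_median")
}

t_ci <- function(x, level = 0.95) {
  n <- length(x)
  se <- stats::sd(x) / sqrt(n)
  half <- stats::qt(1 - (1 - level) / 2, n - 1) * se
  c(mean(x) - half, mean(x) + half)
}

#' Cohort-level action-binding report
#'
#' Runs the group-level binding analysis: MAD-median exclusion on the
#' average perceived keypress time, condition means with t-based 95%
#' CIs (whole sample and per testing-order group), the paired AS vs AO
#' contrast (one-tailed, AS later) with Cohen's dz, and the between
#' order-group contrast on `binding_ms` (two-tailed, Student t) with
#' Cohen's ds.  Excluded participants are reported in the ledger and
#' never enter the statistics.
#'
#' @param summaries a `clockbind_summaries`.
#' @param n_drop leading 'at-12' trials dropped per condition for the
#'   binding estimates (default 0: the raw group analysis).
#' @return list of class `clockbind_binding_report` with `exclusions`,
#'   `kept` (ids), `condition_means`, `paired` (tibble of paired
#'   contrasts), `order_contrast`, `estimates`.
#' @export
cohort_binding_report <- function(summaries, n_drop = 0) {
  stopifnot(inherits(summaries, "clockbind_summaries"))
  excl <- mad_median_exclusions(summaries)
  kept <- excl$participant_id[!excl$flagged]
  est <- binding_estimates(summaries, n_drop = n_drop, participants = kept)
  med <- summaries$medians |>
    dplyr::filter(.data$participant_id %in% kept)
  if (n_drop > 0) {
    med <- summaries$series |>
      dplyr::filter(.data$participant_id %in% kept,
                    .data$at12_index > n_drop) |>
      dplyr::group_by(.data$participant_id, .data$order_group,
                      .data$condition) |>
      dplyr::summarise(median = stats::median(.data$perceived),
                       n_at = dplyr::n(), .groups = "drop")
  }

  scope_means <- function(m, label) {
    m |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(mean = mean(.data$median),
                       ci_low = t_ci(.data$median)[1],
                       ci_high = t_ci(.data$median)[2],
                       n = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(scope = label, .before = 1)
  }
  condition_means <- dplyr::bind_rows(
    scope_means(med, "all"),
    med |>
      dplyr::group_by(.data$order_group) |>
      dplyr::group_map(~ scope_means(.x, .y$order_group)) |>
      dplyr::bind_rows()
  )

  paired_contrast <- function(m, label) {
    w <- tidyr::pivot_wider(m, names_from = "condition",
                            values_from = "median",
                            id_cols = "participant_id")
    if (nrow(w) < 2) return(NULL)
    tt <- tryCatch(paired_t(w$AS, w$AO, tail = "greater"),
                   error = function(e) NULL)
    if (is.null(tt)) return(NULL)
    tibble::tibble(scope = label, t = tt$t, df = tt$df, p = tt$p,
                   dz = cohen_dz(tt$t, nrow(w)), n = nrow(w),
                   mean_binding = mean(w$AS - w$AO))
  }
  paired <- dplyr::bind_rows(
    paired_contrast(med, "all"),
    med |>
      dplyr::group_by(.data$order_group) |>
      dplyr::group_map(~ paired_contrast(.x, .y$order_group)) |>
      dplyr::bind_rows()
  )

  g1 <- est$binding_ms[est$order_group == "AO-AS"]
  g2 <- est$binding_ms[est$order_group == "AS-AO"]
  order_contrast <- NULL
  if (length(g1) >= 2 && length(g2) >= 2) {
    tt <- tryCatch(unpaired_t(g1, g2, tail = "two"), error = function(e) NULL)
    order_contrast <- tibble::tibble(
      t = if (is.null(tt)) NA_real_ else tt$t,
      df = if (is.null(tt)) NA_real_ else tt$df,
      p = if (is.null(tt)) NA_real_ else tt$p,
      ds = if (is.null(tt)) NA_real_ else cohen_ds(tt$t, length(g1), length(g2)),
      mean_ao_first = mean(g1), mean_as_first = mean(g2),
      n_ao_first = length(g1), n_as_first = length(g2))
  }

  structure(list(exclusions = excl, kept = kept,
                 condition_means = condition_means,
                 paired = paired, order_contrast = order_contrast,
                 estimates = est, n_drop = n_drop),
            class = "clockbind_binding_report")
}
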