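#' Ordinary least-squares slope of a perceived-time series
#'
#' Fits `perceived ~ at12_index` by least squares for one participant and
#' condition, quantifying the temporal development of the perceived
#' keypress time over 'at-12' trials (the signature of a carryover from
#' the previously tested condition, or of slow drift).  Implemented in
#' closed form (`slope = cov(x, y) / var(x)`), which is exactly the
#' normal-equation solution for a straight line.
#'
#' @param perceived numeric vector of perceived times (ms).
#' @param index trial indices; defaults to `1..length(perceived)`
#'   ('at-12' acquisition order).
#' @return list with `slope` (ms per 'at-12' trial), `intercept` (ms),
#'   `n`.
#' @export
trial_slope <- function(perceived, index = seq_along(perceived)) {
  if (length(perceived) != length(index)) stop("length mismatch")
  if (length(perceived) < 2) stop("need at least 2 trials")
  if (stats::var(index) == 0) stop("constant predictor")
  slope <- stats::cov(index, perceived) / stats::var(index)
  list(slope = slope, intercept = mean(perceived) - slope * mean(index),
       n = length(perceived))
}

#' Per-participant slopes for every condition series
#'
#' @param summaries a `clockbind_summaries`.
#' @param participants optional restriction (e.g. post-exclusion ids).
#' @return tibble `participant_id`, `order_group`, `condition`, `slope`,
#'   `intercept`, `n_trials`.
#' @export
condition_slopes <- function(summaries, participants = NULL) {
  stopifnot(inherits(summaries, "clockbind_summaries"))
  series <- summaries$series
  if (!is.null(participants)) {
    series <- dplyr::filter(series, .data$participant_id %in% participants)
  }
  series |>
    dplyr::group_by(.data$participant_id, .data$order_group,
                    .data$condition) |>
    dplyr::group_modify(function(g, key) {
      fit <- trial_slope(g$perceived, g$at12_index)
      tibble::tibble(slope = fit$slope, intercept = fit$intercept,
                     n_trials = fit$n)
    }) |>
    dplyr::ungroup()
}

#' Group tests on trial-by-trial slopes
#'
#' Per condition x testing-order group, a two-tailed one-sample t test of
#' the slopes against zero (with Cohen's dz); per condition, the
#' between-group unpaired Student t (with Cohen's ds).  A positive mean
#' slope in a group indicates perceived times developing upward over the
#' condition's 'at-12' trials, a negative one downward - the pattern
#' expected when the condition starts from the other condition's shift
#' and relaxes toward its own.
#'
#' @param slopes tibble from [condition_slopes()].
#' @return list with `one_sample` and `between_groups` tibbles.
#' @export
slope_group_tests <- function(slopes) {
  one_sample <- slopes |>
    dplyr::group_by(.data$condition, .data$order_group) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < 2) stop("group with fewer than 2 slopes")
      ht <- stats::t.test(g$slope, mu = 0)
      tibble::tibble(mean_slope = mean(g$slope),
                     t = unname(ht$statistic), df = unname(ht$parameter),
                     p = ht$p.value, dz = cohen_dz(unname(ht$statistic), nrow(g)),
                     n = nrow(g))
    }) |>
    dplyr::ungroup()
  between <- slopes |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(function(g, key) {
      a <- g$slope[g$order_group == "AO-AS"]
      b <- g$slope[g$order_group == "AS-AO"]
      if (length(a) < 2 || length(b) < 2) stop("group with fewer than 2 slopes")
      tt <- unpaired_t(a, b, tail = "two")
      tibble::tibble(t = tt$t, df = tt$df, p = tt$p,
                     ds = cohen_ds(tt$t, length(a), length(b)),
                     mean_ao_first = mean(a), mean_as_first = mean(b))
    }) |>
    dplyr::ungroup()
  list(one_sample = one_sample, between_groups = between)
}

#' Leave-first-n-trials-out scan of the testing-order effect
#'
#' For each `n` in `0..n_max`, recomputes every participant's
#' `binding_ms` from 'at-12' trials `n+1..end` of each condition and
#' contrasts the two testing-order groups with a two-tailed unpaired
#' Student t.  The row at `n = 0` is the unscanned base contrast.  The
#' scan reveals how far into a condition the carryover from the
#' previously tested condition reaches: once enough leading trials are
#' dropped, the between-group difference should stay non-significant.
#'
#' The scan is run on a fixed participant set (exclusions are decided
#' once, before scanning); if some participant would run out of trials
#' at a given `n`, the scan stops there and records the reason rather
#' than silently unbalancing the groups.
#'
#' @param summaries a `clockbind_summaries`.
#' @param n_max largest number of leading trials to drop (must leave at
#'   least one trial for every participant).
#' @param participants optional restriction (post-exclusion ids).
#' @return list of class `clockbind_scan` with `table` (tibble: one row
#'   per n with per-group mean binding, SE = SD/sqrt(group size), t, df,
#'   p) and `stopped_at`/`stop_reason` when truncated early.
#' @export
leave_first_n_scan <- function(summaries, n_max = 30, participants = NULL) {
  stopifnot(inherits(summaries, "clockbind_summaries"), n_max >= 0)
  series <- summaries$series
  if (!is.null(participants)) {
    series <- dplyr::filter(series, .data$participant_id %in% participants)
  }
  min_at <- series |>
    dplyr::count(.data$participant_id, .data$condition) |>
    dplyr::pull(.data$n) |>
    min()
  stopped_at <- NA_integer_
  stop_reason <- NULL
  if (n_max > min_at - 1) {
    stopped_at <- min_at               # first infeasible n
    stop_reason <- paste0("participant with only ", min_at,
                          " 'at-12' trials in a condition")
    n_max <- min_at - 1
  }
  # per participant: the two condition series in at12_index order
  ord <- order(series$participant_id, series$condition, series$at12_index)
  key <- paste(series$participant_id[ord], series$condition[ord], sep = "\r")
  by_pc <- split(series$perceived[ord], factor(key, levels = unique(key)))
  pc_id <- sub("\r.*$", "", names(by_pc))
  pc_cond <- sub("^.*\r", "", names(by_pc))
  ids <- unique(pc_id)
  grp_of <- series$order_group[match(ids, series$participant_id)]
  ao_of <- by_pc[match(paste(ids, "AO", sep = "\r"), names(by_pc))]
  as_of <- by_pc[match(paste(ids, "AS", sep = "\r"), names(by_pc))]

  rows <- vector("list", n_max + 1)
  for (n in 0:n_max) {
    binding <- vapply(seq_along(ids), function(i) {
      ao <- ao_of[[i]]
      as_ <- as_of[[i]]
      stats::median(as_[(n + 1):length(as_)]) -
        stats::median(ao[(n + 1):length(ao)])
    }, numeric(1))
    g1 <- binding[grp_of == "AO-AS"]
    g2 <- binding[grp_of == "AS-AO"]
    tt <- tryCatch(unpaired_t(g1, g2, tail = "two"), error = function(e) NULL)
    rows[[n + 1]] <- data.frame(
      n_dropped = n,
      mean_ao_first = mean(g1), se_ao_first = stats::sd(g1) / sqrt(length(g1)),
      mean_as_first = mean(g2), se_as_first = stats::sd(g2) / sqrt(length(g2)),
      gap = mean(g1) - mean(g2),
      t = if (is.null(tt)) NA_real_ else tt$t,
      df = if (is.null(tt)) NA_real_ else tt$df,
      p = if (is.null(tt)) NA_real_ else tt$p)
  }
  structure(list(table = tibble::as_tibble(do.call(rbind, rows)),
                 stopped_at = stopped_at, stop_reason = stop_reason),
            class = "clockbind_scan")
}

#' Cut-off from a leave-first-n-out scan
#'
#' The smallest `n` such that the between-group p value exceeds `alpha`
#' for every `m` in `n..horizon` - i.e. dropping `n` leading trials makes
#' the testing-order effect non-significant and it stays so for the rest
#' of the examined range.  Rows with an undefined p (degenerate groups)
#' count as non-significant, since no rejection is possible there.
#'
#' @param scan a `clockbind_scan`.
#' @param alpha significance level (default 0.05).
#' @param horizon largest `n` required to stay non-significant; defaults
#'   to the scan's end.  Capping the horizon below the maximal drop
#'   avoids letting the noisy few-trials-left tail of the scan dictate
#'   the cutoff.
#' @return the cutoff `n*` (integer), or `NA` if no such n exists.
#' @export
cutoff_from_scan <- function(scan, alpha = 0.05, horizon = NULL) {
  stopifnot(inherits(scan, "clockbind_scan"))
  tab <- scan$table
  if (nrow(tab) == 0) stop("empty scan")
  if (is.null(horizon)) horizon <- max(tab$n_dropped)
  if (horizon > max(tab$n_dropped)) stop("horizon exceeds the scan range")
  tab <- tab[tab$n_dropped <= horizon, ]
  ok <- is.na(tab$p) | tab$p > alpha
  # last failing row determines the earliest admissible n
  fail <- which(!ok)
  if (length(fail) == 0) return(0L)
  if (max(fail) == nrow(tab)) return(NA_integer_)
  tab$n_dropped[max(fail) + 1]
}
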