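#' Perceived and actual keypress time
#'
#' In the modified Libet-clock task the physical keypress happens at `t1`
#' and the nearest 12 o'clock crossing of the clock hand at `t2`.  On
#' 'at-12' trials the participant reports the press to have occurred at
#' the crossing, so the *perceived* keypress time relative to the
#' physical press is `t2 - t1` (positive = awareness shifted later than
#' the press).  The *actual* keypress time relative to the crossing is
#' `t1 - t2` (negative = pressed early).  The two are antisymmetric by
#' construction.
#'
#' @param t1,t2 numeric vectors of timestamps in ms (physical press;
#'   12 o'clock crossing).
#' @return numeric vector in ms.
#' @export
perceived_keypress_time <- function(t1, t2) {
  if (anyNA(t1) || anyNA(t2)) stop("missing timestamp")
  t2 - t1
}

#' @rdname perceived_keypress_time
#' @export
actual_keypress_time <- function(t1, t2) {
  if (anyNA(t1) || anyNA(t2)) stop("missing timestamp")
  t1 - t2
}

#' Read and validate a trial-level CSV
#'
#' Expects the dialect written by [write_cohort()]: columns
#' `participant_id`, `order_group` (`AO-AS`/`AS-AO`), `condition`
#' (`AO`/`AS`), `trial_index`, `at12_index` (empty unless the response is
#' 'at'), `t_press_ms`, `t_twelve_ms`, `response`
#' (`before`/`at`/`after`).  Validation is strict-fail: a malformed file
#' is rejected outright rather than partially dropped, so that the
#' participant-exclusion accounting stays unambiguous.
#'
#' @param path CSV file path.
#' @return validated tibble of trials.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  validate_trials(tibble::as_tibble(df))
}

#' @rdname read_trials
#' @param trials a trial table (tibble or data.frame).
#' @export
validate_trials <- function(trials) {
  trials <- tibble::as_tibble(trials)
  need <- c("participant_id", "order_group", "condition", "trial_index",
            "at12_index", "t_press_ms", "t_twelve_ms", "response")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(trials$order_group %in% c("AO-AS", "AS-AO"))) {
    stop("order_group must be 'AO-AS' or 'AS-AO'")
  }
  if (!all(trials$condition %in% c("AO", "AS"))) {
    stop("condition must be 'AO' or 'AS'")
  }
  if (!all(trials$response %in% c("before", "at", "after"))) {
    stop("response must be 'before', 'at' or 'after'")
  }
  if (anyNA(trials$t_press_ms) || anyNA(trials$t_twelve_ms)) {
    stop("missing timestamp")
  }
  if (!all((trials$response == "at") == !is.na(trials$at12_index))) {
    stop("at12_index must be present exactly on 'at' trials")
  }
  if (any(abs(trials$t_press_ms - trials$t_twelve_ms) >= 900)) {
    stop("press further than 900 ms from the 12 o'clock crossing")
  }
  at <- trials$response == "at"
  o <- order(trials$participant_id[at], trials$condition[at],
             trials$trial_index[at])
  key <- paste(trials$participant_id[at], trials$condition[at])[o]
  idx <- trials$at12_index[at][o]
  bad <- tapply(idx, factor(key, levels = unique(key)), function(v) {
    is.unsorted(v, strictly = TRUE)
  })
  if (any(bad)) {
    stop("at12_index must be strictly increasing within participant x condition")
  }
  pg <- unique(paste(trials$participant_id, trials$order_group, sep = "\r"))
  if (anyDuplicated(sub("\r.*$", "", pg))) {
    stop("participant assigned to both order groups")
  }
  trials
}

# median without method dispatch; hot path of the scan and the estimates
median_fast <- function(x) {
  n <- length(x)
  half <- (n + 1L) %/% 2L
  if (n %% 2L == 1L) {
    sort(x, partial = half)[half]
  } else {
    s <- sort(x, partial = c(half, half + 1L))
    (s[half] + s[half + 1L]) / 2
  }
}

#' Per-participant summaries of the trial table
#'
#' Reduces a validated trial table to the quantities the binding analysis
#' runs on: per participant x condition, the ordered series of 'at-12'
#' perceived keypress times (in acquisition order, `at12_index`) with its
#' median; and per participant x response category, the mean actual
#' keypress time, the mean perceived keypress time, and the trial count.
#' Perceived times on 'before'/'after' trials are only approximate (the
#' reported position is not exactly the crossing) and are kept separate
#' from the 'at-12' series.
#'
#' @param trials validated trial table (see [validate_trials()]).
#' @return list of class `clockbind_summaries` with tibbles
#'   * `series`: `participant_id`, `order_group`, `condition`,
#'     `at12_index`, `perceived`;
#'   * `medians`: one row per participant x condition with `median` and
#'     `n_at`;
#'   * `categories`: per participant x response category, `mean_actual`,
#'     `mean_perceived`, `n`.
#' @export
build_summaries <- function(trials) {
  trials <- validate_trials(trials)
  perceived <- perceived_keypress_time(trials$t_press_ms, trials$t_twelve_ms)
  actual <- -perceived

  at <- trials$response == "at"
  o <- order(trials$participant_id[at], trials$condition[at],
             trials$at12_index[at])
  series <- tibble::tibble(
    participant_id = trials$participant_id[at][o],
    order_group = trials$order_group[at][o],
    condition = trials$condition[at][o],
    at12_index = trials$at12_index[at][o],
    perceived = perceived[at][o]
  )
  key <- factor(paste(series$participant_id, series$order_group,
                      series$condition, sep = "\r"),
                levels = unique(paste(series$participant_id,
                                      series$order_group,
                                      series$condition, sep = "\r")))
  med <- tapply(series$perceived, key, median_fast)
  n_at <- tapply(series$perceived, key, length)
  parts <- do.call(rbind, strsplit(names(med), "\r", fixed = TRUE))
  medians <- tibble::tibble(participant_id = parts[, 1],
                            order_group = parts[, 2],
                            condition = parts[, 3],
                            median = as.numeric(med),
                            n_at = as.integer(n_at))
  cnt <- table(medians$participant_id)
  missing_all <- setdiff(unique(trials$participant_id), names(cnt))
  if (any(cnt < 2) || length(missing_all) > 0) {
    stop("participant(s) with zero 'at-12' trials in a condition: ",
         paste(c(names(cnt)[cnt < 2], missing_all), collapse = ", "))
  }
  ckey <- factor(paste(trials$participant_id, trials$order_group,
                       trials$response, sep = "\r"))
  cparts <- do.call(rbind, strsplit(levels(ckey), "\r", fixed = TRUE))
  categories <- tibble::tibble(
    participant_id = cparts[, 1],
    order_group = cparts[, 2],
    response = cparts[, 3],
    mean_actual = as.numeric(tapply(actual, ckey, mean)),
    mean_perceived = as.numeric(tapply(perceived, ckey, mean)),
    n = as.integer(tapply(actual, ckey, length))
  )
  structure(list(series = series, medians = medians, categories = categories),
            class = "clockbind_summaries")
}

#' Validity report for the before/at/after timing judgement
#'
#' Checks that the trial-end judgement tracks the physical press: the
#' actual keypress time should be ordered before < at < after across
#' response categories.  Group means of the per-participant mean actual
#' times are reported per category, together with paired t contrasts
#' (before vs at; at vs after; both two-tailed) and the paired contrast
#' of before vs after trial counts, each with Cohen's dz.  As a
#' secondary check, the (approximate) AS-AO perceived-time contrast
#' within the 'before' and 'after' categories is reported (one-tailed,
#' AS later than AO), computed from trial-level category means per
#' participant x condition.
#'
#' @param trials validated trial table.
#' @return list of class `clockbind_validity` with `category_means`
#'   (tibble), `contrasts` (tibble of paired tests), `count_contrast`,
#'   `binding_in_category` and `empty_categories`.
#' @export
response_validity_report <- function(trials) {
  trials <- validate_trials(trials)
  trials <- dplyr::mutate(
    trials,
    perceived = perceived_keypress_time(.data$t_press_ms, .data$t_twelve_ms),
    actual = actual_keypress_time(.data$t_press_ms, .data$t_twelve_ms)
  )
  per_part <- trials |>
    dplyr::group_by(.data$participant_id, .data$response) |>
    dplyr::summarise(mean_actual = mean(.data$actual),
                     n = dplyr::n(), .groups = "drop") |>
    tidyr::complete(.data$participant_id, response = c("before", "at", "after"),
                    fill = list(n = 0L))
  empty <- per_part |>
    dplyr::group_by(.data$response) |>
    dplyr::summarise(all_empty = all(.data$n == 0), .groups = "drop") |>
    dplyr::filter(.data$all_empty) |>
    dplyr::pull(.data$response)

  category_means <- per_part |>
    dplyr::filter(.data$n > 0) |>
    dplyr::group_by(.data$response) |>
    dplyr::summarise(sd_actual = stats::sd(.data$mean_actual),
                     mean_actual = mean(.data$mean_actual),
                     n_participants = dplyr::n(), .groups = "drop") |>
    dplyr::select("response", "mean_actual", "sd_actual", "n_participants")

  wide <- per_part |>
    dplyr::select("participant_id", "response", "mean_actual") |>
    tidyr::pivot_wider(names_from = "response", values_from = "mean_actual")
  pair <- function(x, y, label) {
    keep <- stats::complete.cases(x, y)
    if (sum(keep) < 2) return(NULL)
    tt <- paired_t(y[keep], x[keep], tail = "two")
    tibble::tibble(contrast = label, t = tt$t, df = tt$df, p = tt$p,
                   dz = cohen_dz(tt$t, sum(keep)), n = sum(keep))
  }
  contrasts <- dplyr::bind_rows(
    pair(wide$before, wide$at, "at - before"),
    pair(wide$at, wide$after, "after - at")
  )

  counts <- per_part |>
    dplyr::select("participant_id", "response", "n") |>
    tidyr::pivot_wider(names_from = "response", values_from = "n")
  count_contrast <- NULL
  if (all(c("before", "after") %in% names(counts))) {
    ct <- tryCatch(paired_t(counts$before, counts$after, tail = "two"),
                   error = function(e) NULL)
    if (!is.null(ct)) {
      count_contrast <- tibble::tibble(
        contrast = "n(before) - n(after)", t = ct$t, df = ct$df, p = ct$p,
        dz = cohen_dz(ct$t, nrow(counts)),
        mean_before = mean(counts$before), mean_after = mean(counts$after))
    }
  }

  bind_cat <- trials |>
    dplyr::filter(.data$response != "at") |>
    dplyr::group_by(.data$participant_id, .data$response, .data$condition) |>
    dplyr::summarise(m = mean(.data$perceived), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "m")
  binding_in_category <- NULL
  if (all(c("AO", "AS") %in% names(bind_cat))) {
    binding_in_category <- bind_cat |>
      dplyr::group_by(.data$response) |>
      dplyr::group_modify(function(g, key) {
        keep <- stats::complete.cases(g$AS, g$AO)
        if (sum(keep) < 2) return(tibble::tibble())
        tt <- paired_t(g$AS[keep], g$AO[keep], tail = "greater")
        tibble::tibble(t = tt$t, df = tt$df, p = tt$p,
                       dz = cohen_dz(tt$t, sum(keep)),
                       mean_binding = mean(g$AS[keep] - g$AO[keep]))
      }) |>
      dplyr::ungroup()
  }

  structure(list(category_means = category_means, contrasts = contrasts,
                 count_contrast = count_contrast,
                 binding_in_category = binding_in_category,
                 empty_categories = empty),
            class = "clockbind_validity")
}
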