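#' Read a PDI-21 questionnaire CSV
#'
#' Expects the wide dialect written by [write_cohort()]:
#' `participant_id` plus, for each item i in 1..21, `endorsed_i` (0/1)
#' and `distress_i`, `preoccupation_i`, `conviction_i` (1-5 when
#' endorsed, empty otherwise).
#'
#' @param path CSV file path.
#' @return tibble of PDI records.
#' @export
read_pdi <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    na.strings = ""))
}

pdi_item_cols <- function(kind) paste0(kind, "_", 1:21)

#' Score the PDI-21 questionnaire
#'
#' The overall score sums, over endorsed items, 1 point for the
#' endorsement plus the 1-5 distress, preoccupation and conviction
#' ratings, giving a range of 0-336 (21 x (1 + 5 + 5 + 5)).  Records
#' with any missing answer (an item left blank, or a rating missing on
#' an endorsed item) are marked incomplete and score `NA`; the analysis
#' drops them with a ledger entry rather than imputing.
#'
#' @param pdi tibble from [read_pdi()] (or the `pdi` element of a
#'   simulated cohort).
#' @return tibble `participant_id`, `overall_score`, `complete`.
#' @export
pdi_overall_score <- function(pdi) {
  need <- c("participant_id", pdi_item_cols("endorsed"),
            pdi_item_cols("distress"), pdi_item_cols("preoccupation"),
            pdi_item_cols("conviction"))
  miss <- setdiff(need, names(pdi))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  end <- as.matrix(pdi[, pdi_item_cols("endorsed")])
  di <- as.matrix(pdi[, pdi_item_cols("distress")])
  pr <- as.matrix(pdi[, pdi_item_cols("preoccupation")])
  co <- as.matrix(pdi[, pdi_item_cols("conviction")])
  ok_range <- function(m) is.na(m) | (m >= 1 & m <= 5)
  if (!all(end %in% c(0, 1, NA)) || !all(ok_range(di)) ||
      !all(ok_range(pr)) || !all(ok_range(co))) {
    stop("PDI answers out of range")
  }
  ratings_ok <- (end == 1 & !is.na(di) & !is.na(pr) & !is.na(co)) |
    (end == 0)
  complete <- !is.na(end) & ratings_ok
  complete[is.na(complete)] <- FALSE
  row_complete <- rowSums(complete) == 21L
  pts <- end * (1 + di + pr + co)
  pts[end == 0] <- 0
  score <- rowSums(pts)
  score[!row_complete] <- NA_real_
  tibble::tibble(participant_id = pdi$participant_id,
                 overall_score = as.integer(round(score)),
                 complete = row_complete)
}

#' Boxplot (1.5 IQR) outlier rule
#'
#' Flags values outside `[Q1 - 1.5*IQR, Q3 + 1.5*IQR]`, the fence that
#' standard boxplot whiskers use.  Quartiles use the linear-interpolation
#' convention (`stats::quantile()` type 7); the flag set can depend on
#' this convention, so it is fixed and documented.
#'
#' @param values numeric vector (length >= 4).
#' @return logical vector of flags.
#' @export
boxplot_outliers <- function(values) {
  if (length(values) < 4) stop("need at least 4 values")
  if (anyNA(values)) stop("missing values")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr
}

#' Pearson correlation with a seeded percentile-bootstrap CI
#'
#' Computes the sample Pearson correlation, a p value from the exact t
#' transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with `df = n - 2`
#' (one- or two-tailed), and a percentile bootstrap 95% confidence
#' interval from `n_boot` resamples of the (x, y) pairs drawn with
#' replacement under the given seed.
#'
#' @param x,y paired numeric vectors, length >= 4.
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed integer seed for the bootstrap.
#' @param tail `"greater"` (positive correlation expected, default),
#'   `"less"` or `"two"`.
#' @param level CI level (default 0.95).
#' @return list of class `clockbind_correlation` with `r`, `n`, `t`,
#'   `df`, `p`, `tail`, `ci_low`, `ci_high`, `n_boot`, `seed`.
#' @export
pearson_bootstrap <- function(x, y, n_boot = 2000, seed = 1L,
                              tail = "greater", level = 0.95) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  n <- length(x)
  if (n < 4) stop("need at least 4 pairs")
  if (anyNA(x) || anyNA(y)) stop("missing values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  r <- stats::cor(x, y)
  tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- switch(tail,
              greater = stats::pt(tt, n - 2, lower.tail = FALSE),
              less = stats::pt(tt, n - 2),
              two = 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE),
              stop("tail must be 'two', 'greater' or 'less'"))
  boot_r <- withr::with_seed(as.integer(seed), {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    apply(idx, 2, function(i) {
      xi <- x[i]; yi <- y[i]
      if (stats::sd(xi) == 0 || stats::sd(yi) == 0) NA_real_
      else stats::cor(xi, yi)
    })
  })
  ci <- stats::quantile(boot_r, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  structure(list(r = r, n = n, t = tt, df = n - 2, p = p, tail = tail,
                 ci_low = ci[1], ci_high = ci[2],
                 n_boot = n_boot, seed = as.integer(seed)),
            class = "clockbind_correlation")
}

#' Delusional ideation vs action-binding correlation
#'
#' Joins the per-participant binding strength (`binding_t` from
#' [binding_estimates()], by default computed with the first 10 'at-12'
#' trials of each condition dropped) with the PDI-21 overall score,
#' drops incomplete PDI records, excludes outliers on either variable by
#' the boxplot rule (union of the two flag sets), and reports the
#' one-tailed Pearson correlation with a seeded percentile-bootstrap CI.
#' The exclusion ledger keeps the accounting explicit:
#' `n = n_in - n_incomplete - n_boxplot`.
#'
#' @param estimates tibble from [binding_estimates()] (post MAD-median
#'   exclusion).
#' @param pdi PDI table (see [read_pdi()]).
#' @param n_boot,seed,tail passed to [pearson_bootstrap()].
#' @return list of class `clockbind_delusion_result`: the
#'   `clockbind_correlation` under `correlation`, the analysis `data`
#'   (tibble `participant_id`, `pdi_score`, `binding_t`, `excluded`,
#'   `reason`), and a `ledger` of counts.
#' @export
delusion_binding_analysis <- function(estimates, pdi, n_boot = 2000,
                                      seed = 1L, tail = "greater") {
  scores <- pdi_overall_score(pdi)
  joined <- dplyr::inner_join(
    dplyr::select(estimates, "participant_id", "binding_t"),
    scores, by = "participant_id")
  if (any(is.na(joined$binding_t))) {
    stop("binding_t undefined for some participants")
  }
  n_in <- nrow(joined)
  incomplete <- !joined$complete
  work <- joined[!incomplete, ]
  if (nrow(work) < 4) stop("fewer than 4 usable pairs")
  flag <- boxplot_outliers(work$overall_score) |
    boxplot_outliers(work$binding_t)
  kept <- work[!flag, ]
  if (nrow(kept) < 4) stop("fewer than 4 usable pairs after exclusion")
  corr <- pearson_bootstrap(kept$overall_score, kept$binding_t,
                            n_boot = n_boot, seed = seed, tail = tail)
  data <- tibble::tibble(
    participant_id = c(joined$participant_id[incomplete],
                       work$participant_id),
    pdi_score = c(joined$overall_score[incomplete], work$overall_score),
    binding_t = c(joined$binding_t[incomplete], work$binding_t),
    excluded = c(rep(TRUE, sum(incomplete)), flag),
    reason = c(rep("incomplete_pdi", sum(incomplete)),
               ifelse(flag, "boxplot", NA_character_)))
  ledger <- list(n_in = n_in, n_incomplete = sum(incomplete),
                 n_boxplot = sum(flag), n_used = nrow(kept))
  structure(list(correlation = corr, data = data, ledger = ledger),
            class = "clockbind_delusion_result")
}
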