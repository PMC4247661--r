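#' Activity-intensity cut-points
#'
#' Count thresholds partitioning worn epochs into sedentary, light and
#' moderate-to-vigorous (MVPA) intensity. Defaults are the standard
#' hip-worn adult cut-points: vertical axis sedentary < 100 cpm and
#' MVPA >= 1952 cpm (light is 100-1951); vector magnitude sedentary
#' < 200 cpm and MVPA >= 2690 cpm. Classification is
#' `sedentary if count < sedentary_upper`, `mvpa if count >= mvpa_lower`,
#' light otherwise, so the three classes partition the worn time with no
#' gap or overlap.
#'
#' @param axis `"vertical"` or `"vm"`.
#' @param sedentary_upper,mvpa_lower Optional overrides (cpm);
#'   `0 < sedentary_upper < mvpa_lower` required.
#' @return A list of class `"intensity_cutpoints"`.
#' @export
intensity_cutpoints <- function(axis = c("vertical", "vm"),
                                sedentary_upper = NULL, mvpa_lower = NULL) {
  axis <- match.arg(axis)
  if (is.null(sedentary_upper))
    sedentary_upper <- if (axis == "vertical") 100 else 200
  if (is.null(mvpa_lower))
    mvpa_lower <- if (axis == "vertical") 1952 else 2690
  stopifnot(sedentary_upper > 0, sedentary_upper < mvpa_lower)
  structure(list(axis = axis, sedentary_upper = sedentary_upper,
                 mvpa_lower = mvpa_lower),
            class = "intensity_cutpoints")
}

#' Classify epochs by intensity
#'
#' @param count Nonnegative count value(s) (cpm); vertical counts are
#'   integers, vector-magnitude counts may be real.
#' @param cutpoints An [intensity_cutpoints()].
#' @return Factor with levels `sedentary`, `light`, `mvpa` (same length as
#'   `count`).
#' @examples
#' cp <- intensity_cutpoints("vertical")
#' classify_epoch(c(99, 100, 1951, 1952), cp)
#' @export
classify_epoch <- function(count, cutpoints = intensity_cutpoints("vertical")) {
  stopifnot(inherits(cutpoints, "intensity_cutpoints"), all(count >= 0))
  lab <- ifelse(count < cutpoints$sedentary_upper, "sedentary",
                ifelse(count >= cutpoints$mvpa_lower, "mvpa", "light"))
  factor(lab, levels = c("sedentary", "light", "mvpa"))
}

#' Per-day wear and intensity summary
#'
#' For each calendar date the series spans, tallies minutes of wear under the
#' mask and minutes of each intensity class among worn epochs only (non-worn
#' epochs contribute to nothing). A day is valid when it has at least
#' `valid_min` (default 600, i.e. 10 h) minutes of wear. The intensity
#' minutes always sum exactly to the wear minutes.
#'
#' @param series An [epoch_series()].
#' @param mask A `"wear_mask"` (or logical vector) aligned to `series`.
#' @param cutpoints An [intensity_cutpoints()]; its `axis` selects the count
#'   signal (vertical counts or vector magnitude) that is classified.
#' @param valid_min Valid-day wear threshold in minutes (default 600).
#' @return Data.frame with one row per date: `date`, `wear_min`,
#'   `sedentary_min`, `light_min`, `mvpa_min`, `valid`.
#' @export
summarize_days <- function(series, mask,
                           cutpoints = intensity_cutpoints("vertical"),
                           valid_min = 600) {
  stopifnot(inherits(series, "epoch_series"),
            length(mask) == n_epochs(series),
            inherits(cutpoints, "intensity_cutpoints"))
  counts <- axis_counts(series, cutpoints$axis)
  dates <- epoch_dates(series)
  worn <- as.logical(mask)
  cls <- classify_epoch(counts, cutpoints)
  all_dates <- sort(unique(dates))
  f <- factor(dates, levels = as.character(all_dates))
  tab_wear <- tapply(worn, f, sum, default = 0)
  per_class <- function(lv)
    tapply(worn & cls == lv, f, sum, default = 0)
  out <- data.frame(
    date = all_dates,
    wear_min = as.numeric(tab_wear),
    sedentary_min = as.numeric(per_class("sedentary")),
    light_min = as.numeric(per_class("light")),
    mvpa_min = as.numeric(per_class("mvpa"))
  )
  out$valid <- out$wear_min >= valid_min
  out
}

#' Subject-level summary over valid days
#'
#' Aggregates a subject's per-day summaries: number of valid days, the >= 1
#' and >= 4 valid-day eligibility flags, and mean daily wear / sedentary /
#' light / MVPA minutes over valid days only. Subjects without a valid day
#' are flagged ineligible and carry `NA` means.
#'
#' @param days Data.frame from [summarize_days()].
#' @param subject_id Optional identifier carried through.
#' @return One-row data.frame: `subject_id`, `n_days`, `n_valid_days`,
#'   `has_1_valid`, `has_4_valid`, and `wear_min`, `sedentary_min`,
#'   `light_min`, `mvpa_min` means over valid days.
#' @export
summarize_subject <- function(days, subject_id = NA_character_) {
  stopifnot(is.data.frame(days))
  v <- days[days$valid, , drop = FALSE]
  nv <- nrow(v)
  mean_or_na <- function(x) if (nv > 0) mean(x) else NA_real_
  data.frame(
    subject_id = subject_id,
    n_days = nrow(days),
    n_valid_days = nv,
    has_1_valid = nv >= 1,
    has_4_valid = nv >= 4,
    wear_min = mean_or_na(v$wear_min),
    sedentary_min = mean_or_na(v$sedentary_min),
    light_min = mean_or_na(v$light_min),
    mvpa_min = mean_or_na(v$mvpa_min),
    stringsAsFactors = FALSE
  )
}

#' Cohort summary
#'
#' Medians and interquartile ranges of subject-level mean daily metrics
#' across subjects with at least one valid day, plus sample-size accounting
#' against the eligible cohort: counts/percents with >= 1 and >= 4 valid
#' days, median (IQR) number of valid days, and the percent of subjects with
#' more than 7 valid days (the mail-noise diagnostic for a 7-day wear
#' protocol). Quantiles use linear interpolation between closest ranks
#' (R default, type 7).
#'
#' @param subjects Data.frame of stacked [summarize_subject()] rows.
#' @param eligible_n Size of the eligible cohort (at least `nrow(subjects)`).
#' @return A list of class `"cohort_summary"`: `eligible_n`, `n_subjects`,
#'   `n_ge1_valid`, `pct_ge1_valid`, `n_ge4_valid`, `pct_ge4_valid`,
#'   `pct_gt7_valid`, `valid_days` (median/IQR), and `metrics` (data.frame of
#'   median, q25, q75 per daily metric).
#' @export
summarize_cohort <- function(subjects, eligible_n = nrow(subjects)) {
  stopifnot(is.data.frame(subjects), nrow(subjects) >= 1L,
            eligible_n >= nrow(subjects))
  el <- subjects[subjects$has_1_valid, , drop = FALSE]
  q <- function(x) stats::quantile(x, c(.5, .25, .75), names = FALSE, type = 7)
  metrics <- c("wear_min", "sedentary_min", "light_min", "mvpa_min")
  mt <- if (nrow(el) > 0) t(vapply(metrics, function(m) q(el[[m]]), numeric(3)))
        else matrix(NA_real_, 4, 3, dimnames = list(metrics, NULL))
  mt <- data.frame(metric = metrics, median = mt[, 1], q25 = mt[, 2],
                   q75 = mt[, 3], row.names = NULL)
  vd <- if (nrow(el) > 0) q(el$n_valid_days) else rep(NA_real_, 3)
  structure(list(
    eligible_n = eligible_n,
    n_subjects = nrow(subjects),
    n_ge1_valid = sum(subjects$has_1_valid),
    pct_ge1_valid = 100 * sum(subjects$has_1_valid) / eligible_n,
    n_ge4_valid = sum(subjects$has_4_valid),
    pct_ge4_valid = 100 * sum(subjects$has_4_valid) / eligible_n,
    pct_gt7_valid = 100 * sum(subjects$n_valid_days > 7) / eligible_n,
    valid_days = c(median = vd[1], q25 = vd[2], q75 = vd[3]),
    metrics = mt
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, digits = 1, ...) {
  cat(sprintf("<cohort_summary> eligible n = %d; with data = %d\n",
              x$eligible_n, x$n_subjects))
  cat(sprintf("  >=1 valid day: %d (%.1f%%)   >=4 valid days: %d (%.1f%%)   >7 valid days: %.1f%%\n",
              x$n_ge1_valid, x$pct_ge1_valid, x$n_ge4_valid, x$pct_ge4_valid,
              x$pct_gt7_valid))
  cat(sprintf("  valid days: median %.0f (IQR %.0f, %.0f)\n",
              x$valid_days[1], x$valid_days[2], x$valid_days[3]))
  m <- x$metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-13s median %7.1f (IQR %7.1f, %7.1f) min/day\n",
                m$metric[i], m$median[i], m$q25[i], m$q75[i]))
  invisible(x)
}
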