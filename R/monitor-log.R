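#' Participant monitor log
#'
#' Per-day participant-reported record of the date, wake time, monitor-on
#' time, monitor-off time and bed time. Any component — the date, the
#' hour/minute of a time, or its AM/PM indicator — may be missing; the
#' detailed-log wear mask and the limited-log (dates-only) restriction both
#' derive from this object.
#'
#' Times are stored in 12-hour-clock components (`*_hour` in 1..12, `*_min`
#' in 0..59, `*_mer` in `"AM"`/`"PM"`/`NA`) for the four fields `wake`, `on`,
#' `off`, `bed`.
#'
#' @param subject_id Subject identifier string.
#' @param days A data.frame with one row per log day: column `date` (`Date`,
#'   `NA` allowed) plus the 12 time-component columns. Missing components
#'   are `NA`.
#' @return An object of class `"monitor_log"`.
#' @export
monitor_log <- function(subject_id, days) {
  needed <- c("date", paste0(rep(c("wake", "on", "off", "bed"), each = 3),
                             c("_hour", "_min", "_mer")))
  stopifnot(is.data.frame(days), all(needed %in% names(days)))
  days$date <- as.Date(days$date)
  pd <- days$date[!is.na(days$date)]
  if (anyDuplicated(pd)) stop("duplicate dates in monitor log")
  for (f in c("wake", "on", "off", "bed")) {
    h <- days[[paste0(f, "_hour")]]
    if (any(!is.na(h) & (h < 1 | h > 12)))
      stop(sprintf("%s_hour must be on the 12-hour clock (1-12)", f))
  }
  structure(list(subject_id = subject_id, days = days),
            class = "monitor_log")
}

#' @export
print.monitor_log <- function(x, ...) {
  cat(sprintf("<monitor_log> subject %s: %d day(s), %d with a date\n",
              x$subject_id, nrow(x$days), sum(!is.na(x$days$date))))
  invisible(x)
}

n_log_days <- function(log) nrow(log$days)

# parse "6:30 AM" / "7:00" / "" into hour/min/meridiem components
parse_clock_token <- function(token, row = NA, field = "") {
  token <- trimws(token)
  if (is.na(token) || !nzchar(token))
    return(list(hour = NA_integer_, min = NA_integer_, mer = NA_character_))
  m <- regmatches(token, regexec(
    "^([0-9]{1,2}):([0-9]{2})(?:\\s*([AaPp])\\.?[Mm]\\.?)?$", token))[[1L]]
  if (length(m) == 0L)
    stop(sprintf("row %s, field '%s': unparseable time token '%s'",
                 row, field, token))
  hour <- as.integer(m[2L]); minute <- as.integer(m[3L])
  if (hour < 1 || hour > 12 || minute > 59)
    stop(sprintf("row %s, field '%s': time '%s' not on the 12-hour clock",
                 row, field, token))
  mer <- if (nzchar(m[4L])) ifelse(toupper(m[4L]) == "A", "AM", "PM")
         else NA_character_
  list(hour = hour, min = minute, mer = mer)
}

format_clock <- function(hour, minute, mer) {
  ifelse(is.na(hour) | is.na(minute), "",
         paste0(hour, ":", formatC(minute, width = 2, flag = "0"),
                ifelse(is.na(mer), "", paste0(" ", mer))))
}

# minutes since midnight, NA if any needed component is missing
clock_minutes <- function(hour, minute, mer) {
  ifelse(is.na(hour) | is.na(minute) | is.na(mer), NA_real_,
         (hour %% 12) * 60 + minute + ifelse(mer == "PM", 720, 0))
}

#' Read a participant monitor-log CSV
#'
#' Expects a CSV with header `date,wake,on,off,bed` and one row per day.
#' Dates are ISO (`YYYY-MM-DD`); times are 12-hour clock tokens such as
#' `"6:30 AM"`; a token without an AM/PM indicator (`"7:00"`) is kept with a
#' missing meridiem, and empty cells are fully missing. Missingness is
#' preserved — no imputation happens at read time (see [impute_meridiem()]).
#'
#' @param path Path to the log CSV.
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#' @return A [monitor_log()].
#' @export
read_log <- function(path, subject_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, colClasses = "character")
  needed <- c("date", "wake", "on", "off", "bed")
  if (!all(needed %in% names(df)))
    stop(sprintf("%s: log must have columns %s", path,
                 paste(needed, collapse = ", ")))
  days <- data.frame(date = as.Date(ifelse(nzchar(trimws(df$date)),
                                           trimws(df$date), NA)))
  for (f in c("wake", "on", "off", "bed")) {
    parsed <- lapply(seq_len(nrow(df)), function(i)
      parse_clock_token(df[[f]][i], row = i, field = f))
    days[[paste0(f, "_hour")]] <- vapply(parsed, `[[`, integer(1), "hour")
    days[[paste0(f, "_min")]] <- vapply(parsed, `[[`, integer(1), "min")
    days[[paste0(f, "_mer")]] <- vapply(parsed, `[[`, character(1), "mer")
  }
  monitor_log(subject_id, days)
}

#' Write a monitor log as CSV
#'
#' Inverse of [read_log()] for the same dialect.
#'
#' @param log A [monitor_log()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_log <- function(log, path) {
  stopifnot(inherits(log, "monitor_log"))
  d <- log$days
  out <- data.frame(
    date = ifelse(is.na(d$date), "", format(d$date, "%Y-%m-%d")))
  for (f in c("wake", "on", "off", "bed"))
    out[[f]] <- format_clock(d[[paste0(f, "_hour")]], d[[paste0(f, "_min")]],
                             d[[paste0(f, "_mer")]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-day log completeness flags
#'
#' Derives, for each log day, the three missingness categories used for
#' monitor logs: a missing date; a missing time (hour and/or minute of the
#' monitor-on or monitor-off time); and a missing AM/PM indicator for the
#' on or off time.
#'
#' @param log A [monitor_log()].
#' @return Data.frame with columns `day`, `missing_date`, `missing_time`,
#'   `missing_meridiem`.
#' @export
log_completeness <- function(log) {
  d <- log$days
  data.frame(
    day = seq_len(nrow(d)),
    missing_date = is.na(d$date),
    missing_time = (is.na(d$on_hour) | is.na(d$on_min)) |
      (is.na(d$off_hour) | is.na(d$off_min)),
    missing_meridiem = (is.na(d$on_mer) & !(is.na(d$on_hour) & is.na(d$on_min))) |
      (is.na(d$off_mer) & !(is.na(d$off_hour) & is.na(d$off_min)))
  )
}

#' Tabulate log missingness across a cohort
#'
#' Counts and percentages of logs missing the date, the on/off time, or the
#' on/off AM/PM indicator, per day index — the structure used to describe
#' monitor-log completeness in mail-based cohorts.
#'
#' @param logs A list of [monitor_log()] objects.
#' @return Data.frame with one row per day index: `day`, `n_logs`, counts
#'   `date`, `time`, `meridiem`, and the corresponding `*_pct` percentages
#'   (of `n_logs`).
#' @export
tabulate_missingness <- function(logs) {
  stopifnot(length(logs) >= 1L)
  comp <- lapply(logs, log_completeness)
  max_day <- max(vapply(comp, nrow, integer(1)))
  out <- data.frame(day = seq_len(max_day), n_logs = 0L,
                    date = 0L, time = 0L, meridiem = 0L)
  for (cc in comp) {
    k <- nrow(cc)
    out$n_logs[seq_len(k)] <- out$n_logs[seq_len(k)] + 1L
    out$date[seq_len(k)] <- out$date[seq_len(k)] + cc$missing_date
    out$time[seq_len(k)] <- out$time[seq_len(k)] + cc$missing_time
    out$meridiem[seq_len(k)] <- out$meridiem[seq_len(k)] + cc$missing_meridiem
  }
  out$date_pct <- 100 * out$date / out$n_logs
  out$time_pct <- 100 * out$time / out$n_logs
  out$meridiem_pct <- 100 * out$meridiem / out$n_logs
  out
}

#' Impute missing AM/PM indicators in a monitor log
#'
#' Applies a deterministic rule sequence to resolve missing meridiem
#' (AM/PM) components, never overwriting a recorded value:
#' \enumerate{
#'   \item Default windows: wake and monitor-on times default to AM when the
#'     hour is in 4-11; bed and monitor-off times default to PM when the
#'     hour is in 5-11, and to AM when the hour is 12 (the 12 AM = midnight,
#'     12 PM = noon convention).
#'   \item Ordering: a still-missing on-time meridiem is resolved so that
#'     on >= wake when the wake time is known; a missing off-time meridiem so
#'     that off <= bed and off > on when those are known. A choice is made
#'     only when exactly one meridiem satisfies all applicable constraints.
#'   \item Anything unresolved stays missing.
#' }
#' Contradictions (no choice satisfies the ordering) leave the field missing
#' and are flagged in the audit.
#'
#' @param log A [monitor_log()].
#' @return A list with elements `log` (the imputed [monitor_log()]) and
#'   `audit` (data.frame with one row per touched field: `day`, `field`,
#'   `rule` — `"default_window"`, `"ordering"` or `"contradiction"` — and the
#'   `imputed` value, `NA` for contradictions).
#' @export
impute_meridiem <- function(log) {
  stopifnot(inherits(log, "monitor_log"))
  d <- log$days
  audit <- list()
  note <- function(day, field, rule, value)
    audit[[length(audit) + 1L]] <<- data.frame(
      day = day, field = field, rule = rule, imputed = value,
      stringsAsFactors = FALSE)

  for (i in seq_len(nrow(d))) {
    # rule 1: default meridiem windows
    for (f in c("wake", "on")) {
      h <- d[[paste0(f, "_hour")]][i]
      if (is.na(d[[paste0(f, "_mer")]][i]) && !is.na(h) && h >= 4 && h <= 11) {
        d[[paste0(f, "_mer")]][i] <- "AM"
        note(i, f, "default_window", "AM")
      }
    }
    for (f in c("off", "bed")) {
      h <- d[[paste0(f, "_hour")]][i]
      if (is.na(d[[paste0(f, "_mer")]][i]) && !is.na(h)) {
        if (h >= 5 && h <= 11) {
          d[[paste0(f, "_mer")]][i] <- "PM"
          note(i, f, "default_window", "PM")
        } else if (h == 12) {
          d[[paste0(f, "_mer")]][i] <- "AM"
          note(i, f, "default_window", "AM")
        }
      }
    }
    # rule 2: ordering-based resolution for what remains
    wake <- clock_minutes(d$wake_hour[i], d$wake_min[i], d$wake_mer[i])
    bed <- clock_minutes(d$bed_hour[i], d$bed_min[i], d$bed_mer[i])
    if (is.na(d$on_mer[i]) && !is.na(d$on_hour[i]) && !is.na(d$on_min[i])) {
      ok <- vapply(c("AM", "PM"), function(mm) {
        v <- clock_minutes(d$on_hour[i], d$on_min[i], mm)
        is.na(wake) || v >= wake
      }, logical(1))
      if (sum(ok) == 1L) {
        d$on_mer[i] <- names(ok)[ok]
        note(i, "on", "ordering", names(ok)[ok])
      } else if (sum(ok) == 0L) {
        note(i, "on", "contradiction", NA_character_)
      }
    }
    on <- clock_minutes(d$on_hour[i], d$on_min[i], d$on_mer[i])
    if (is.na(d$off_mer[i]) && !is.na(d$off_hour[i]) && !is.na(d$off_min[i])) {
      ok <- vapply(c("AM", "PM"), function(mm) {
        v <- clock_minutes(d$off_hour[i], d$off_min[i], mm)
        (is.na(bed) || v <= bed) && (is.na(on) || v > on)
      }, logical(1))
      if (sum(ok) == 1L) {
        d$off_mer[i] <- names(ok)[ok]
        note(i, "off", "ordering", names(ok)[ok])
      } else if (sum(ok) == 0L) {
        note(i, "off", "contradiction", NA_character_)
      }
    }
  }
  audit <- if (length(audit)) do.call(rbind, audit)
           else data.frame(day = integer(), field = character(),
                           rule = character(), imputed = character(),
                           stringsAsFactors = FALSE)
  list(log = monitor_log(log$subject_id, d), audit = audit)
}

#' Detailed-log wear mask
#'
#' Builds the wear mask defined by the participant's own record: epochs
#' within `[on, off)` on each log day that has a complete date, on time and
#' off time (after [impute_meridiem()]) are wear; everything else —
#' including every epoch of days with any required component still missing —
#' is non-wear. A day whose off time does not fall after its on time
#' contributes no wear and is flagged. Log dates outside the recorded series
#' are ignored with a warning (monitors start recording before delivery, so
#' this is expected).
#'
#' @param log A [monitor_log()], normally after imputation.
#' @param series The [epoch_series()] to align to.
#' @return A `"wear_mask"` with attribute `dropped_days` (integer indices of
#'   log days that contributed no wear for lack of data or ordering).
#' @export
detailed_log_mask <- function(log, series) {
  stopifnot(inherits(log, "monitor_log"), inherits(series, "epoch_series"))
  d <- log$days
  n <- n_epochs(series)
  wear <- logical(n)
  dates <- epoch_dates(series)
  tod <- epoch_minute_of_day(series)
  dropped <- integer()
  series_dates <- unique(dates)
  for (i in seq_len(nrow(d))) {
    on <- clock_minutes(d$on_hour[i], d$on_min[i], d$on_mer[i])
    off <- clock_minutes(d$off_hour[i], d$off_min[i], d$off_mer[i])
    if (is.na(d$date[i]) || is.na(on) || is.na(off)) {
      dropped <- c(dropped, i)
      next
    }
    if (off <= on) {
      dropped <- c(dropped, i)
      next
    }
    if (!(d$date[i] %in% series_dates)) {
      warning(sprintf("subject %s: log date %s not covered by the recorded series",
                      log$subject_id, format(d$date[i])))
      next
    }
    wear[dates == d$date[i] & tod >= on & tod < off] <- TRUE
  }
  out <- new_wear_mask(wear, "detailed_log", "log")
  attr(out, "dropped_days") <- dropped
  out
}

#' Restrict an algorithm wear mask to limited-log dates
#'
#' The limited-log hybrid uses only the dates the participant recorded (no
#' on/off times): every epoch whose calendar date is absent from the log's
#' present dates is forced to non-wear, while epochs on log dates keep the
#' algorithm's classification. This removes mail-transit days that zero-run
#' algorithms mistake for wear. The operation never increases wear time and
#' is idempotent.
#'
#' @param mask A `"wear_mask"` from a non-wear algorithm, aligned to `series`.
#' @param log A [monitor_log()] with at least one present date; a log with no
#'   dates at all is a refusal (such subjects are excluded, as participants
#'   without logs are excluded from log-based processing).
#' @param series The [epoch_series()] the mask is aligned to.
#' @return A `"wear_mask"` with method tag `"limited_log_<algorithm>"`.
#' @export
limited_log_restrict <- function(mask, log, series) {
  stopifnot(inherits(log, "monitor_log"), inherits(series, "epoch_series"),
            length(mask) == n_epochs(series))
  log_dates <- log$days$date[!is.na(log$days$date)]
  if (length(log_dates) == 0L)
    stop("limited_log_restrict: log has no usable dates; subject excluded")
  wear <- as.logical(mask) & (epoch_dates(series) %in% log_dates)
  new_wear_mask(wear, paste0("limited_log_", attr(mask, "method")),
                attr(mask, "axis"))
}
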