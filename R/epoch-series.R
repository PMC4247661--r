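#' Minute-epoch triaxial count series
#'
#' Container for one subject's accelerometer record at 60-s resolution:
#' one row per epoch with counts for the vertical (axis1), anterior-posterior
#' (axis2) and medio-lateral (axis3) axes. Epochs are contiguous: epoch k
#' covers `[start_time + 60*(k-1), start_time + 60*k)` seconds. Timestamps
#' are timezone-naive local time (stored as UTC internally); only 60-s
#' epochs are supported.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param start_time Start of the first epoch; `POSIXct` or an ISO-8601
#'   string (`"YYYY-MM-DDTHH:MM:SS"`, the `T` may be a space).
#' @param axis1,axis2,axis3 Nonnegative integer-valued count vectors of equal
#'   length (counts per minute).
#' @param epoch_seconds Epoch length in seconds; must be 60.
#'
#' @return An object of class `"epoch_series"`: a list with elements
#'   `subject_id`, `start_time`, `epoch_seconds`, `axis1`, `axis2`, `axis3`.
#' @examples
#' es <- epoch_series("S1", "2012-03-01T00:00:00",
#'                    axis1 = c(0, 3, 100), axis2 = c(0, 4, 200),
#'                    axis3 = c(0, 0, 200))
#' compute_vm(es)
#' @export
epoch_series <- function(subject_id, start_time, axis1, axis2, axis3,
                         epoch_seconds = 60L) {
  if (!is.character(subject_id) || length(subject_id) != 1L || is.na(subject_id))
    stop("'subject_id' must be a single non-missing string")
  start_time <- parse_epoch_time(start_time)
  if (length(epoch_seconds) != 1L || is.na(epoch_seconds) || epoch_seconds != 60)
    stop("unsupported epoch resolution: epoch_seconds must be 60")
  axes <- list(axis1 = axis1, axis2 = axis2, axis3 = axis3)
  n <- length(axis1)
  for (nm in names(axes)) {
    v <- axes[[nm]]
    if (length(v) != n)
      stop("axis vectors must have equal length")
    check_counts(v, nm)
  }
  structure(
    list(subject_id = subject_id, start_time = start_time,
         epoch_seconds = 60L,
         axis1 = as.integer(round(axis1)),
         axis2 = as.integer(round(axis2)),
         axis3 = as.integer(round(axis3))),
    class = "epoch_series"
  )
}

# counts must be finite, nonnegative and integer-valued
check_counts <- function(v, what, rows = NULL) {
  if (length(v) == 0L) return(invisible(TRUE))
  if (!is.numeric(v)) stop(sprintf("%s: counts must be numeric", what))
  bad <- !is.finite(v) | v < 0 | v != round(v)
  if (any(bad)) {
    i <- which(bad)[1L]
    row <- if (is.null(rows)) i else rows[i]
    stop(sprintf("%s: invalid count %s at row %d (counts must be nonnegative integers)",
                 what, format(v[i]), row))
  }
  invisible(TRUE)
}

parse_epoch_time <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(format(x, "%Y-%m-%d %H:%M:%S"), tz = "UTC"))
  if (!is.character(x) || length(x) != 1L)
    stop("'start_time' must be POSIXct or an ISO-8601 string")
  x2 <- sub("T", " ", x, fixed = TRUE)
  out <- tryCatch(
    as.POSIXct(x2, tz = "UTC",
               tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M")),
    error = function(e) NA)
  if (is.na(out)) stop(sprintf("malformed timestamp: '%s'", x))
  out
}

#' @export
print.epoch_series <- function(x, ...) {
  n <- n_epochs(x)
  cat(sprintf("<epoch_series> subject %s: %d epochs of %ds\n",
              x$subject_id, n, x$epoch_seconds))
  cat(sprintf("  start: %s", format(x$start_time, "%Y-%m-%dT%H:%M:%S")))
  if (n > 0)
    cat(sprintf("   end: %s", format(x$start_time + 60 * n, "%Y-%m-%dT%H:%M:%S")))
  cat("\n")
  invisible(x)
}

#' Number of epochs in a series
#' @param series An [epoch_series()].
#' @return Integer count of 60-s epochs.
#' @export
n_epochs <- function(series) length(series$axis1)

#' Epoch start times and calendar dates
#'
#' `epoch_times()` returns the start timestamp of every epoch;
#' `epoch_dates()` the local calendar date each epoch starts on (epochs are
#' attributed to the date containing their start, so a series crossing
#' midnight splits at 00:00).
#'
#' @param series An [epoch_series()].
#' @return `POSIXct` / `Date` vector of length `n_epochs(series)`.
#' @export
epoch_times <- function(series) {
  series$start_time + 60 * (seq_len(n_epochs(series)) - 1)
}

#' @rdname epoch_times
#' @export
epoch_dates <- function(series) {
  # series times are tz-naive (UTC-backed), so day arithmetic is integer
  secs <- as.numeric(series$start_time) + 60 * (seq_len(n_epochs(series)) - 1)
  as.Date(floor(secs / 86400), origin = "1970-01-01")
}

# minute of local day [0, 1440) for each epoch start
epoch_minute_of_day <- function(series) {
  secs <- as.numeric(series$start_time) + 60 * (seq_len(n_epochs(series)) - 1)
  (secs %% 86400) / 60
}

#' Vector-magnitude counts
#'
#' Per-epoch Euclidean norm of the three axis counts:
#' `sqrt(axis1^2 + axis2^2 + axis3^2)`. The value is kept as an unrounded
#' real number; all vector-magnitude thresholds in this package compare
#' against the real value, since rounding would move boundary epochs across
#' cut-points.
#'
#' @param series An [epoch_series()].
#' @return Numeric vector of vector-magnitude counts per minute, same length
#'   and alignment as the series.
#' @export
compute_vm <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  sqrt(as.numeric(series$axis1)^2 + as.numeric(series$axis2)^2 +
         as.numeric(series$axis3)^2)
}

#' Extract the count signal for a given axis
#'
#' @param series An [epoch_series()].
#' @param axis `"vertical"` (axis1 counts) or `"vm"` (vector magnitude).
#' @return Numeric count vector.
#' @export
axis_counts <- function(series, axis = c("vertical", "vm")) {
  axis <- match.arg(axis)
  if (axis == "vertical") as.numeric(series$axis1) else compute_vm(series)
}
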