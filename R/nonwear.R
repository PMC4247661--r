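#' Non-wear rule parameters
#'
#' Parameter bundle for the zero-run non-wear detection rules. Use the
#' convenience constructors [troiano_params()] and [choi_params()] for the
#' published defaults; all constants are overridable.
#'
#' @param rule `"troiano"` or `"choi"`.
#' @param axis `"vertical"` (axis1 cpm) or `"vm"` (vector magnitude).
#' @param window_min Minimum span length, in minutes, for a non-wear bout
#'   (Troiano 60; Choi 90).
#' @param tolerance_upper Troiano only: counts strictly below this value may
#'   interrupt a zero span (vertical 100, matching the sedentary cut-point;
#'   vm 200). Interrupting epochs must satisfy `0 < count < tolerance_upper`;
#'   zero epochs are span members, not interruptions.
#' @param spike_tolerance_min Troiano only: maximum length, in minutes, of a
#'   single tolerated interruption run (2).
#' @param max_interruption_runs Troiano only: maximum number of tolerated
#'   interruption runs per span. Default `Inf` (the NHANES reference reading:
#'   any number of separate 1-2 min interruptions); set to 1 for the stricter
#'   literal reading of "1-2 minutes".
#' @param artifactual_interrupt_upper Choi only: maximum interruption run
#'   length in minutes (2).
#' @param flank_zero_min Choi only: minutes of consecutive zeros required
#'   around an interruption (30).
#' @param flank_mode Choi only: `"both"` (default; the validated rule —
#'   30 zero minutes required upstream AND downstream) or `"either"` (the
#'   literal "up or downstream" reading).
#' @return A list of class `"nonwear_params"`.
#' @export
nonwear_params <- function(rule = c("troiano", "choi"),
                           axis = c("vertical", "vm"),
                           window_min = if (rule == "troiano") 60L else 90L,
                           tolerance_upper = if (axis == "vertical") 100 else 200,
                           spike_tolerance_min = 2L,
                           max_interruption_runs = Inf,
                           artifactual_interrupt_upper = 2L,
                           flank_zero_min = 30L,
                           flank_mode = c("both", "either")) {
  rule <- match.arg(rule)
  axis <- match.arg(axis)
  flank_mode <- match.arg(flank_mode)
  stopifnot(window_min >= 1, tolerance_upper > 0, spike_tolerance_min >= 0,
            artifactual_interrupt_upper >= 0, flank_zero_min >= 1,
            max_interruption_runs >= 0)
  structure(list(rule = rule, axis = axis,
                 window_min = as.integer(window_min),
                 tolerance_upper = tolerance_upper,
                 spike_tolerance_min = as.integer(spike_tolerance_min),
                 max_interruption_runs = max_interruption_runs,
                 artifactual_interrupt_upper = as.integer(artifactual_interrupt_upper),
                 flank_zero_min = as.integer(flank_zero_min),
                 flank_mode = flank_mode),
            class = "nonwear_params")
}

#' @rdname nonwear_params
#' @export
troiano_params <- function(axis = c("vertical", "vm"), ...) {
  axis <- match.arg(axis)
  nonwear_params(rule = "troiano", axis = axis, ...)
}

#' @rdname nonwear_params
#' @export
choi_params <- function(axis = c("vertical", "vm"), ...) {
  axis <- match.arg(axis)
  nonwear_params(rule = "choi", axis = axis, ...)
}

new_wear_mask <- function(wear, method, axis) {
  structure(as.logical(wear), method = method, axis = axis,
            class = "wear_mask")
}

#' @export
print.wear_mask <- function(x, ...) {
  cat(sprintf("<wear_mask> %s/%s: %d epochs, %d wear min, %d non-wear min\n",
              attr(x, "method"), attr(x, "axis"), length(x),
              sum(x), sum(!x)))
  invisible(x)
}

check_nonwear_input <- function(counts) {
  if (!is.numeric(counts)) stop("counts must be a numeric vector")
  if (length(counts) && (anyNA(counts) || any(!is.finite(counts)) || any(counts < 0)))
    stop("counts must be finite and nonnegative")
  as.numeric(counts)
}

#' Troiano non-wear detection
#'
#' Classifies each epoch of a count sequence as wear or non-wear using the
#' NHANES zero-run rule: non-wear is a maximal span of zero-count epochs of
#' total length at least `window_min` (60) minutes, optionally interrupted by
#' runs of 1-2 consecutive epochs with counts strictly between 0 and
#' `tolerance_upper` (100 cpm on the vertical axis). Any epoch at or above
#' the tolerance, or any interruption run of 3 or more epochs, terminates the
#' span. Spans begin and end on zero epochs (an interruption at a span edge
#' is not a span member), and tolerated interruption epochs inside a
#' qualifying span are counted as non-wear.
#'
#' `troiano_nonwear_vm()` is the vector-magnitude modification: identical
#' logic with interruptions tolerated at `0 < vm < 200`, keeping the
#' tolerance consistent with the VM sedentary cut-point.
#'
#' @param counts Per-epoch counts (vertical cpm, or vm for the VM variant);
#'   finite and nonnegative. VM values may be non-integer.
#' @param params A [nonwear_params()] with `rule = "troiano"`.
#' @return A `"wear_mask"`: logical vector, `TRUE` = worn.
#' @seealso [choi_nonwear()], [oracle_nonwear()]
#' @export
troiano_nonwear <- function(counts, params = troiano_params("vertical")) {
  stopifnot(inherits(params, "nonwear_params"), params$rule == "troiano")
  counts <- check_nonwear_input(counts)
  nonwear <- troiano_spans(counts, params)
  new_wear_mask(!nonwear, "troiano", params$axis)
}

#' @rdname troiano_nonwear
#' @export
troiano_nonwear_vm <- function(counts, params = troiano_params("vm")) {
  stopifnot(params$axis == "vm", params$tolerance_upper == 200 ||
              !missing(params))
  troiano_nonwear(counts, params)
}

# run-length span algebra for the Troiano rule
troiano_spans <- function(counts, params) {
  n <- length(counts)
  nonwear <- logical(n)
  if (n == 0L) return(nonwear)
  tol <- params$tolerance_upper
  spike <- params$spike_tolerance_min
  cap <- params$max_interruption_runs
  win <- params$window_min

  cat <- ifelse(counts == 0, 0L, ifelse(counts < tol, 1L, 2L))
  r <- rle(cat)
  vals <- r$values
  lens <- r$lengths
  # tolerable-count runs longer than the spike tolerance are blockers
  vals[vals == 1L & lens > spike] <- 2L
  ends <- cumsum(lens)
  starts <- ends - lens + 1L

  # maximal stretches of non-blocker runs
  blocker <- vals == 2L
  seg_id <- cumsum(blocker)
  for (sid in unique(seg_id[!blocker])) {
    idx <- which(seg_id == sid & !blocker)
    # trim leading/trailing interruption runs: spans start and end on zeros
    zidx <- idx[vals[idx] == 0L]
    if (length(zidx) == 0L) next
    idx <- idx[idx >= min(zidx) & idx <= max(zidx)]
    z <- idx[vals[idx] == 0L]  # zero runs, in order
    m <- length(z)
    if (cap >= m - 1L) {
      total <- ends[max(idx)] - starts[min(idx)] + 1L
      if (total >= win) nonwear[starts[min(idx)]:ends[max(idx)]] <- TRUE
    } else {
      # strict reading: at most `cap` interruption runs per span; mark the
      # union of all qualifying zero-run windows
      for (i in seq_len(m)) {
        jmax <- min(m, i + cap)
        for (j in i:jmax) {
          total <- ends[z[j]] - starts[z[i]] + 1L
          if (total >= win) nonwear[starts[z[i]]:ends[z[j]]] <- TRUE
        }
      }
    }
  }
  nonwear
}

#' Choi non-wear detection
#'
#' Classifies each epoch as wear or non-wear using the Choi rule: non-wear is
#' a maximal span of zero-count epochs of total length at least `window_min`
#' (90) minutes, allowing nonzero interruption runs of at most
#' `artifactual_interrupt_upper` (2) consecutive epochs when the interruption
#' is flanked by at least `flank_zero_min` (30) consecutive zero-count
#' epochs within the span. The default `flank_mode = "both"` requires the
#' 30-min zero run on both sides (the validated rule); `"either"` accepts one
#' side. The same criteria apply unchanged to vector-magnitude input; there
#' is no count-magnitude cap on interruptions.
#'
#' @inheritParams troiano_nonwear
#' @param params A [nonwear_params()] with `rule = "choi"`.
#' @return A `"wear_mask"`: logical vector, `TRUE` = worn.
#' @seealso [troiano_nonwear()], [oracle_nonwear()]
#' @export
choi_nonwear <- function(counts, params = choi_params("vertical")) {
  stopifnot(inherits(params, "nonwear_params"), params$rule == "choi")
  counts <- check_nonwear_input(counts)
  nonwear <- choi_spans(counts, params)
  new_wear_mask(!nonwear, "choi", params$axis)
}

choi_spans <- function(counts, params) {
  n <- length(counts)
  nonwear <- logical(n)
  if (n == 0L) return(nonwear)
  win <- params$window_min
  maxint <- params$artifactual_interrupt_upper
  flank <- params$flank_zero_min
  both <- params$flank_mode == "both"

  r <- rle(counts == 0)
  lens <- r$lengths
  iszero <- r$values
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  zi <- which(iszero)
  if (length(zi) == 0L) return(nonwear)

  # link consecutive zero runs when the nonzero run between them is a
  # tolerated interruption
  m <- length(zi)
  linked <- logical(max(m - 1L, 0L))
  if (m > 1L) for (k in seq_len(m - 1L)) {
    # zero runs are separated by exactly one nonzero run
    nz <- zi[k] + 1L
    ok_len <- lens[nz] <= maxint
    fl_up <- lens[zi[k]] >= flank
    fl_dn <- lens[zi[k + 1L]] >= flank
    linked[k] <- ok_len && if (both) (fl_up && fl_dn) else (fl_up || fl_dn)
  }
  chain_id <- c(0L, cumsum(!linked))
  for (cid in unique(chain_id)) {
    members <- zi[chain_id == cid]
    s <- starts[members[1L]]
    e <- ends[members[length(members)]]
    if (e - s + 1L >= win) nonwear[s:e] <- TRUE
  }
  nonwear
}

#' Run a non-wear rule on an epoch series
#'
#' Convenience wrapper selecting the count signal (`axis_counts()`) and the
#' published parameter defaults for the requested rule/axis combination.
#'
#' @param series An [epoch_series()].
#' @param rule `"troiano"` or `"choi"`.
#' @param axis `"vertical"` or `"vm"`.
#' @param params Optional [nonwear_params()] override.
#' @return A `"wear_mask"` aligned to `series`.
#' @export
nonwear_mask <- function(series, rule = c("troiano", "choi"),
                         axis = c("vertical", "vm"), params = NULL) {
  rule <- match.arg(rule)
  axis <- match.arg(axis)
  if (is.null(params)) params <- nonwear_params(rule, axis)
  counts <- axis_counts(series, axis)
  if (rule == "troiano") troiano_nonwear(counts, params)
  else choi_nonwear(counts, params)
}

#' Wear minutes under a mask
#'
#' Counts worn epochs (minutes), either in total or partitioned by local
#' calendar date. Epochs are attributed to the date containing their start
#' time, so a worn stretch crossing midnight splits at 00:00.
#'
#' @param mask A `"wear_mask"` (or logical vector), `TRUE` = worn.
#' @param series The [epoch_series()] the mask is aligned to (needed for
#'   `by = "calendar_day"`).
#' @param by `"total"` or `"calendar_day"`.
#' @return For `"total"`, a single number of minutes. For `"calendar_day"`,
#'   a named numeric vector of minutes per date (all dates the series spans,
#'   zeros included).
#' @export
wear_minutes <- function(mask, series = NULL, by = c("total", "calendar_day")) {
  by <- match.arg(by)
  if (by == "total") return(sum(mask))
  stopifnot(inherits(series, "epoch_series"), length(mask) == n_epochs(series))
  d <- epoch_dates(series)
  out <- tapply(as.logical(mask), d, sum)
  res <- as.numeric(out)
  names(res) <- names(out)
  res
}
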