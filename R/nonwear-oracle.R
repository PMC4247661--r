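#' Reference non-wear oracle (sequential span scan)
#'
#' Independent reference implementation of the Troiano and Choi non-wear
#' contracts, used to validate the production run-length implementations.
#' It scans the raw count sequence epoch by epoch, growing every candidate
#' span from each zero-run start and marking the union of all qualifying
#' spans. It shares no code with [troiano_nonwear()] / [choi_nonwear()] and
#' is deliberately simple rather than fast; input length is capped.
#'
#' @param counts Per-epoch counts, finite and nonnegative.
#' @param rule `"troiano"` or `"choi"`.
#' @param params A [nonwear_params()] for the matching rule.
#' @return A `"wear_mask"` (`TRUE` = worn).
#' @export
oracle_nonwear <- function(counts, rule = c("troiano", "choi"),
                           params = nonwear_params(match.arg(rule))) {
  rule <- match.arg(rule)
  counts <- check_nonwear_input(counts)
  if (length(counts) > 20160L)
    stop("oracle_nonwear: refusing sequences longer than 20,160 epochs")
  nonwear <- if (rule == "troiano") oracle_troiano(counts, params)
             else oracle_choi(counts, params)
  new_wear_mask(!nonwear, paste0("oracle_", rule), params$axis)
}

oracle_troiano <- function(counts, params) {
  n <- length(counts)
  nonwear <- logical(n)
  tol <- params$tolerance_upper
  spike <- params$spike_tolerance_min
  cap <- params$max_interruption_runs
  win <- params$window_min
  i <- 1L
  while (i <= n) {
    if (counts[i] != 0) { i <- i + 1L; next }
    if (i > 1L && counts[i - 1L] == 0) { i <- i + 1L; next }  # not a zero-run start
    # grow a candidate span from this zero-run start
    last_zero <- i
    runs_used <- 0L
    k <- i + 1L
    repeat {
      if (k > n) break
      if (counts[k] == 0) { last_zero <- k; k <- k + 1L; next }
      # nonzero run starting at k: tolerated interruption?
      m <- k
      while (m <= n && counts[m] > 0 && counts[m] < tol) m <- m + 1L
      runlen <- m - k
      tolerated <- runlen >= 1L && runlen <= spike &&
        m <= n && counts[m] == 0 && runs_used + 1L <= cap
      if (!tolerated) break
      runs_used <- runs_used + 1L
      k <- m
    }
    if (last_zero - i + 1L >= win) nonwear[i:last_zero] <- TRUE
    # with unlimited interruption runs the span is maximal, so no start
    # inside it can reach further; under a finite cap later starts may
    i <- if (is.infinite(cap)) last_zero + 1L else i + 1L
  }
  nonwear
}

oracle_choi <- function(counts, params) {
  n <- length(counts)
  nonwear <- logical(n)
  win <- params$window_min
  maxint <- params$artifactual_interrupt_upper
  flank <- params$flank_zero_min
  both <- params$flank_mode == "both"
  i <- 1L
  while (i <= n) {
    if (counts[i] != 0) { i <- i + 1L; next }
    if (i > 1L && counts[i - 1L] == 0) { i <- i + 1L; next }
    span_start <- i
    k <- i
    last_zero_end <- i
    repeat {
      # advance through the current zero run
      z_start <- k
      while (k <= n && counts[k] == 0) k <- k + 1L
      z_len <- k - z_start
      last_zero_end <- k - 1L
      if (k > n) break
      # nonzero run
      m <- k
      while (m <= n && counts[m] != 0) m <- m + 1L
      nz_len <- m - k
      if (m > n) break  # interruption runs to record end: not a span member
      # zero run after the interruption
      z2 <- m
      while (z2 <= n && counts[z2] == 0) z2 <- z2 + 1L
      next_z_len <- z2 - m
      fl <- if (both) (z_len >= flank && next_z_len >= flank)
            else (z_len >= flank || next_z_len >= flank)
      if (nz_len <= maxint && fl) k <- m else break
    }
    if (last_zero_end - span_start + 1L >= win)
      nonwear[span_start:last_zero_end] <- TRUE
    i <- last_zero_end + 1L
  }
  nonwear
}
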