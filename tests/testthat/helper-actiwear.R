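# Block-structured random count sequences for non-wear testing: alternating
# runs of zeros, sub-tolerance counts, counts between the two tolerances
# (100/200) and clearly-active counts, so every rule branch is exercised.
random_count_seq <- function(n, mean_run = 40) {
  out <- numeric(0)
  while (length(out) < n) {
    len <- stats::rgeom(1, 1 / mean_run) + 1
    type <- sample(4, 1, prob = c(0.45, 0.20, 0.15, 0.20))
    vals <- switch(type,
                   rep(0, len),
                   sample(1:99, len, replace = TRUE),
                   sample(100:250, len, replace = TRUE),
                   sample(100:3000, len, replace = TRUE))
    out <- c(out, vals)
  }
  out[seq_len(n)]
}

# all-zero flat series helper
flat_series <- function(n, a1 = 0, a2 = 0, a3 = 0, id = "T1",
                        start = "2012-03-01T00:00:00") {
  epoch_series(id, start, rep(a1, n), rep(a2, n), rep(a3, n))
}

# brute-force two-sided signed-rank p over all 2^n sign assignments,
# mid-ranked ties, zeros dropped; independent of the package's DP path
enumerate_wilcoxon_p <- function(d) {
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0) return(1)
  r <- rank(abs(nz))
  V <- sum(r[nz > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  W <- signs %*% r
  p_le <- mean(W <= V + 1e-9)
  p_ge <- mean(W >= V - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# pure run-length non-wear: maximal zero runs >= window  (reduction oracle)
runlength_nonwear <- function(counts, window) {
  r <- rle(counts == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nw <- logical(length(counts))
  for (k in which(r$values & r$lengths >= window)) nw[starts[k]:ends[k]] <- TRUE
  nw
}

# one-row log-day constructor with all components settable
log_day <- function(date = NA, wake = c(NA, NA, NA), on = c(NA, NA, NA),
                    off = c(NA, NA, NA), bed = c(NA, NA, NA)) {
  row <- data.frame(date = as.Date(date))
  for (f in c("wake", "on", "off", "bed")) {
    v <- get(f)
    row[[paste0(f, "_hour")]] <- as.integer(v[1])
    row[[paste0(f, "_min")]] <- as.integer(v[2])
    row[[paste0(f, "_mer")]] <- if (is.na(v[3])) NA_character_ else as.character(v[3])
  }
  row
}

make_log <- function(..., id = "L1") {
  monitor_log(id, do.call(rbind, list(...)))
}
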