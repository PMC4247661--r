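#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided signed-rank test of paired measurements with the conventions
#' pinned for cross-implementation agreement: zero differences are dropped
#' (signed-rank convention), tied absolute differences receive mid-ranks,
#' and the p-value is exact — computed from the full distribution of the
#' positive-rank sum over all sign assignments — when the number of non-zero
#' differences is at most `exact_limit` (25), otherwise a continuity-corrected
#' normal approximation with tie-corrected variance is used. The exact
#' distribution is computed by counting over integer doubled mid-ranks, so
#' ties are handled exactly as well.
#'
#' @param a,b Paired numeric vectors (condition A and condition B), equal
#'   length, no missing values.
#' @param exact_limit Largest number of non-zero differences for which the
#'   exact distribution is enumerated (default 25).
#' @return A list of class `"wilcoxon_sr"`: `statistic` (V, the positive-rank
#'   sum of `b - a`), `p_value` (two-sided), `n_pairs`, `n_nonzero`,
#'   `method` (`"exact"`, `"asymptotic"` or `"degenerate"`), `degenerate`
#'   (TRUE when all differences are zero, in which case `p_value` is 1).
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))  # p = 0.0625
#' @export
wilcoxon_signed_rank <- function(a, b, exact_limit = 25L) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == length(b),
            !anyNA(a), !anyNA(b), length(a) >= 1L)
  d <- b - a
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0L)
    return(structure(list(statistic = 0, p_value = 1, n_pairs = length(d),
                          n_nonzero = 0L, method = "degenerate",
                          degenerate = TRUE), class = "wilcoxon_sr"))
  r <- rank(abs(nz))  # mid-ranks for ties
  V <- sum(r[nz > 0])
  if (n <= exact_limit) {
    p <- signed_rank_exact_p(r, V)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- V - mu
    corr <- sign(z) * 0.5
    z <- (z - corr) / sqrt(sigma2)
    p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
    method <- "asymptotic"
  }
  structure(list(statistic = V, p_value = p, n_pairs = length(d),
                 n_nonzero = n, method = method, degenerate = FALSE),
            class = "wilcoxon_sr")
}

# exact two-sided p for the positive mid-rank sum V given ranks r:
# distribution of sum of a random subset of r over all 2^n sign vectors,
# counted over doubled ranks (integers even with .5 mid-ranks)
signed_rank_exact_p <- function(r, V) {
  w <- as.integer(round(2 * r))
  total <- sum(w)
  f <- numeric(total + 1L)  # f[s+1] = number of subsets with doubled-sum s
  f[1L] <- 1
  for (wi in w) {
    g <- f
    g[(wi + 1L):(total + 1L)] <- g[(wi + 1L):(total + 1L)] + f[1L:(total + 1L - wi)]
    f <- g
  }
  v2 <- round(2 * V)
  tot <- 2^length(w)
  p_le <- sum(f[seq_len(v2 + 1L)]) / tot
  p_ge <- sum(f[(v2 + 1L):(total + 1L)]) / tot
  min(1, 2 * min(p_le, p_ge))
}

#' @export
print.wilcoxon_sr <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: V = %g, p = %.4g (%s; %d non-zero of %d pairs)\n",
              x$statistic, x$p_value, x$method, x$n_nonzero, x$n_pairs))
  if (x$degenerate) cat("  all differences zero: degenerate\n")
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Mean bias of paired measurements and 95% limits of agreement:
#' `bias = mean(b - a)` and `bias +/- 1.96 * sd(b - a)` with the sample
#' (n - 1) standard deviation.
#'
#' @param a,b Paired numeric vectors (condition A and B); at least 2 pairs.
#' @return A list of class `"bland_altman"`: `bias`, `sd_diff`, `loa_lower`,
#'   `loa_upper`, `n`, plus `means` and `diffs` for plotting.
#' @export
bland_altman <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == length(b),
            !anyNA(a), !anyNA(b))
  if (length(a) < 2L) stop("bland_altman: need at least 2 pairs")
  d <- b - a
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
                 n = length(d), means = (a + b) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.2f, 95%% LoA (%.2f, %.2f), n = %d\n",
              x$bias, x$loa_lower, x$loa_upper, x$n))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "Mean of methods",
                              ylab = "Difference (B - A)", ...) {
  graphics::plot(x$means, x$diffs, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = x$bias, lty = 1)
  graphics::abline(h = c(x$loa_lower, x$loa_upper), lty = 2)
  invisible(x)
}
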