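# Independent oracles and small generators shared across the test files.

# Explicit cumulative-distribution scan for the percentage method: walks
# the normalised cumulative sum day by day. Kept deliberately naive and
# separate from the package implementation.
scan_season_oracle <- function(doy, conc, alpha = 2.5) {
  conc[is.na(conc)] <- 0
  total <- sum(conc)
  frac <- cumsum(conc) / total
  sos <- NA_integer_
  eos <- NA_integer_
  for (i in seq_along(doy)) {
    if (is.na(sos) && frac[i] >= alpha / 100) sos <- doy[i]
    if (is.na(eos) && frac[i] >= (100 - alpha) / 100) eos <- doy[i]
  }
  list(sos = sos, eos = eos)
}

# Normal-equations least squares, independent of lm / lm.fit.
normal_equations_ols <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# A random but valid pollen series (nonzero total, some zero days).
random_pollen_series <- function(seed) {
  set.seed(seed)
  n <- sample(30:150, 1L)
  doy <- sort(sample.int(366L, n))
  conc <- stats::rexp(n, rate = 1 / sample(5:50, 1L))
  conc[sample.int(n, max(1L, n %/% 8L))] <- 0
  daily_pollen_series("RND", "Betula", 2000L, doy, conc)
}

# Sorting-based order-statistics quantile (linear interpolation between
# order statistics, the standard sample-quantile definition).
sort_quantile_oracle <- function(x, p) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
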