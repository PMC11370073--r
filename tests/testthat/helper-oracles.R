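# Independent brute-force oracles used to check the package's fast paths.

# Run-length scanner for non-wear: walks the window sequence one element at
# a time, tracking the current sub-threshold run.
brute_nonwear <- function(sds, window_s = 15, sd_threshold = 0.013,
                          min_duration_min = 30) {
  out <- list()
  run_start <- NA
  for (i in seq_along(sds)) {
    if (sds[i] < sd_threshold) {
      if (is.na(run_start)) run_start <- i
    } else if (!is.na(run_start)) {
      out[[length(out) + 1]] <- c(run_start, i - 1)
      run_start <- NA
    }
  }
  if (!is.na(run_start)) out[[length(out) + 1]] <- c(run_start, length(sds))
  keep <- Filter(function(r) (r[2] - r[1] + 1) * window_s >= min_duration_min * 60, out)
  if (length(keep) == 0) {
    return(tibble::tibble(
      start_window = integer(), end_window = integer(),
      n_windows = integer(), duration_min = numeric()
    ))
  }
  tibble::tibble(
    start_window = vapply(keep, function(r) r[1] - 1L, integer(1)),
    end_window = vapply(keep, function(r) r[2] - 1L, integer(1)),
    n_windows = vapply(keep, function(r) r[2] - r[1] + 1L, integer(1)),
    duration_min = vapply(keep, function(r) (r[2] - r[1] + 1) * window_s / 60, numeric(1))
  )
}

# Direct DFT (naive summation) peak frequency of a mean-centred series,
# searching frequencies >= min_freq.
dft_peak_freq <- function(x, sample_rate, min_freq = 0.1) {
  n <- length(x)
  x <- x - mean(x)
  ks <- seq(1L, floor(n / 2))
  freqs <- ks * sample_rate / n
  power <- vapply(ks, function(k) {
    t <- seq_len(n) - 1
    re <- sum(x * cos(-2 * pi * k * t / n))
    im <- sum(x * sin(-2 * pi * k * t / n))
    re^2 + im^2
  }, numeric(1))
  elig <- freqs >= min_freq
  freqs[elig][which.max(power[elig])]
}

# Direct scalar evaluation of the restricted-cubic-spline truncated-power
# formula, one point and one column at a time.
brute_rcs <- function(x, knots) {
  k <- length(knots)
  pos3 <- function(u) if (u > 0) u^3 else 0
  out <- matrix(NA_real_, length(x), k - 1)
  for (i in seq_along(x)) {
    out[i, 1] <- x[i]
    for (j in seq_len(k - 2)) {
      out[i, j + 1] <- (pos3(x[i] - knots[j]) -
        pos3(x[i] - knots[k - 1]) * (knots[k] - knots[j]) / (knots[k] - knots[k - 1]) +
        pos3(x[i] - knots[k]) * (knots[k - 1] - knots[j]) / (knots[k] - knots[k - 1])) /
        (knots[k] - knots[1])^2
    }
  }
  out
}

# Literal evaluation of the guideline rules.
brute_rule <- function(rule_id, tpa, mvpa) {
  switch(rule_id,
    EY_TODDLER = tpa >= 180,
    EY_PRESCHOOL = tpa >= 180 && mvpa >= 60,
    CYP_SCHOOL = mvpa >= 60
  )
}

# Constant-value window features for degenerate-signal checks.
constant_vm_features <- function(value = 1, n = 450, sample_rate = 30) {
  window_features(rep(value, n), sample_rate)
}
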