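# Raw-signal handling: vector magnitude, 15-s windowing, and the fixed
# 25-feature set computed on each window's vector magnitude.

#' Construct a raw recording
#'
#' Container for one subject's tri-axial hip accelerometer recording at a
#' fixed sample rate, in units of gravitational acceleration (g).
#'
#' @param data Data frame with numeric columns `x`, `y`, `z` (acceleration
#'   in g), one row per sample.
#' @param subject_id Subject identifier.
#' @param start_time `POSIXct` timestamp of the first sample (local time).
#' @param sample_rate Sampling frequency in Hz (default 30).
#'
#' @return An object of class `raw_recording`: a list with elements `data`
#'   (tibble of samples), `subject_id`, `start_time`, `sample_rate`.
#' @export
raw_recording <- function(data, subject_id, start_time, sample_rate = 30) {
  if (!is.data.frame(data) || !all(c("x", "y", "z") %in% names(data))) {
    abort_arg("`data` must be a data frame with columns x, y, z.")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    abort_arg("`sample_rate` must be a single positive number.")
  }
  if (!inherits(start_time, "POSIXct")) start_time <- as.POSIXct(start_time, tz = "UTC")
  structure(
    list(
      data = tibble::as_tibble(data[c("x", "y", "z")]),
      subject_id = as.character(subject_id),
      start_time = start_time,
      sample_rate = sample_rate
    ),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  n <- nrow(x$data)
  cat(sprintf(
    "<raw_recording> subject %s: %d samples @ %g Hz (%.1f min), start %s\n",
    x$subject_id, n, x$sample_rate, n / x$sample_rate / 60,
    format(x$start_time, "%Y-%m-%d %H:%M:%S")
  ))
  invisible(x)
}

#' Vector magnitude of a tri-axial signal
#'
#' Per-sample Euclidean norm `sqrt(x^2 + y^2 + z^2)` of the three
#' acceleration axes, collapsing the tri-axial signal to a single series in g.
#'
#' @param x Either a numeric vector of x-axis values, a data frame with
#'   columns `x`, `y`, `z`, or a `raw_recording`.
#' @param y,z Numeric vectors (only when `x` is a vector).
#'
#' @return Numeric vector, same length as the input axes.
#' @export
#'
#' @examples
#' vector_magnitude(3, 4, 12) # 13
vector_magnitude <- function(x, y = NULL, z = NULL) {
  if (inherits(x, "raw_recording")) {
    d <- x$data
    return(sqrt(d$x^2 + d$y^2 + d$z^2))
  }
  if (is.data.frame(x)) {
    if (!all(c("x", "y", "z") %in% names(x))) {
      abort_arg("data frame input must have columns x, y, z.")
    }
    return(sqrt(x$x^2 + x$y^2 + x$z^2))
  }
  if (is.null(y) || is.null(z)) abort_arg("supply y and z alongside a vector x.")
  if (length(y) != length(x) || length(z) != length(x)) {
    abort_arg("axes must have equal length.")
  }
  sqrt(x^2 + y^2 + z^2)
}

#' Segment a recording into non-overlapping windows
#'
#' Splits a recording into consecutive, non-overlapping windows of
#' `window_s` seconds, aligned to the recording start. A trailing partial
#' window is dropped.
#'
#' @param recording A [raw_recording].
#' @param window_s Window length in seconds (default 15).
#'
#' @return A tibble with one row per window: `subject_id`, `window_index`
#'   (0-based), `window_start` (`POSIXct`) and `samples` (list-column of
#'   tibbles with `x`, `y`, `z`).
#' @export
segment_windows <- function(recording, window_s = 15) {
  stopifnot(inherits(recording, "raw_recording"))
  spw <- recording$sample_rate * window_s
  if (abs(spw - round(spw)) > 1e-9) {
    abort_arg("sample_rate * window_s must be an integer number of samples.")
  }
  spw <- as.integer(round(spw))
  n <- nrow(recording$data)
  n_win <- n %/% spw
  if (n_win == 0) {
    return(tibble::tibble(
      subject_id = character(), window_index = integer(),
      window_start = as.POSIXct(character(), tz = "UTC"), samples = list()
    ))
  }
  idx <- seq_len(n_win) - 1L
  samples <- purrr::map(idx, function(i) {
    recording$data[(i * spw + 1L):((i + 1L) * spw), , drop = FALSE]
  })
  tibble::tibble(
    subject_id = recording$subject_id,
    window_index = idx,
    window_start = recording$start_time + idx * window_s,
    samples = samples
  )
}

# Names of the 25 window features, in contract order.
FEATURE_NAMES <- c(
  "vm_mean", "vm_sd", "vm_cv", "vm_min", "vm_max",
  "vm_p10", "vm_p25", "vm_p50", "vm_p75", "vm_p90",
  "vm_iqr", "vm_skew", "vm_kurt", "vm_acf1", "zero_cross",
  "peak_count", "total_power", "dom_freq", "dom_power", "dom_power_frac",
  "dom_freq2", "spec_entropy", "bp_low", "bp_high", "bp_ratio"
)

#' Names of the 25 window features
#'
#' The fixed feature contract used by the activity classifier, all computed
#' on the window's vector magnitude: moments and order statistics
#' (`vm_mean`, `vm_sd`, `vm_cv`, `vm_min`, `vm_max`, percentiles 10/25/50/
#' 75/90, `vm_iqr`, `vm_skew`, `vm_kurt`), temporal structure (`vm_acf1`
#' lag-1 autocorrelation, `zero_cross` zero crossings of the mean-centred
#' signal, `peak_count` local maxima above mean + 1 SD), and spectral
#' summaries of the mean-centred signal (`total_power`, `dom_freq`,
#' `dom_power`, `dom_power_frac`, `dom_freq2`, `spec_entropy`, band powers
#' 0.25-2.5 Hz and 2.5-5 Hz and their ratio).
#'
#' @return Character vector of length 25.
#' @export
feature_names <- function() FEATURE_NAMES

#' Compute the 25-feature vector for one window
#'
#' @param vm Numeric vector: the window's vector magnitude (g), covering
#'   exactly `window_s` seconds at `sample_rate`.
#' @param sample_rate Sampling frequency in Hz.
#' @param window_s Window length in seconds (default 15); used to validate
#'   the sample count.
#'
#' @details The spectrum is the unnormalised periodogram of the
#'   mean-centred, untapered window; frequencies below 0.1 Hz are excluded
#'   from the dominant-frequency search to suppress residual gravity
#'   leakage. Zero-variance windows yield finite features by convention:
#'   skewness, kurtosis, lag-1 autocorrelation and spectral entropy are 0.
#'
#' @return Named numeric vector of length 25 (see [feature_names()]).
#' @export
window_features <- function(vm, sample_rate, window_s = 15) {
  n_expect <- as.integer(round(sample_rate * window_s))
  if (length(vm) != n_expect) {
    abort_arg(sprintf(
      "window has %d samples; expected %d (%g s at %g Hz).",
      length(vm), n_expect, window_s, sample_rate
    ))
  }
  n <- length(vm)
  mu <- mean(vm)
  s <- sd(vm)
  centred <- vm - mu
  qs <- unname(quantile(vm, c(0.10, 0.25, 0.50, 0.75, 0.90), type = 7))

  if (s > 0) {
    m2 <- mean(centred^2)
    skew <- mean(centred^3) / m2^1.5
    kurt <- mean(centred^4) / m2^2 - 3
    acf1 <- sum(centred[-n] * centred[-1]) / sum(centred^2)
  } else {
    skew <- 0; kurt <- 0; acf1 <- 0
  }

  sign_c <- sign(centred)
  nz <- sign_c[sign_c != 0]
  zero_cross <- if (length(nz) > 1) sum(diff(nz) != 0) else 0
  thr <- mu + s
  inner <- vm[2:(n - 1)]
  peak_count <- sum(inner > vm[1:(n - 2)] & inner >= vm[3:n] & inner > thr)

  total_power <- mean(centred^2)

  # one-sided periodogram of the mean-centred window (DC bin is ~0)
  spec <- fft(centred)
  half <- seq(2L, floor(n / 2) + 1L)
  pw <- (Mod(spec[half])^2) / n^2 * 2
  if (n %% 2 == 0) pw[length(pw)] <- pw[length(pw)] / 2 # Nyquist not doubled
  freqs <- (half - 1L) * sample_rate / n

  if (total_power > 0) {
    elig <- which(freqs >= 0.1)
    ord <- elig[order(pw[elig], decreasing = TRUE)]
    dom_freq <- freqs[ord[1]]
    dom_power <- pw[ord[1]]
    dom_power_frac <- dom_power / sum(pw)
    dom_freq2 <- if (length(ord) > 1) freqs[ord[2]] else 0
    p_norm <- pw / sum(pw)
    p_pos <- p_norm[p_norm > 0]
    spec_entropy <- -sum(p_pos * log(p_pos)) / log(length(pw))
    bp_low <- sum(pw[freqs >= 0.25 & freqs < 2.5])
    bp_high <- sum(pw[freqs >= 2.5 & freqs <= 5])
    bp_ratio <- bp_low / (bp_high + 1e-12)
  } else {
    dom_freq <- 0; dom_power <- 0; dom_power_frac <- 0; dom_freq2 <- 0
    spec_entropy <- 0; bp_low <- 0; bp_high <- 0; bp_ratio <- 0
  }

  out <- c(
    mu, s, if (mu > 0) s / mu else 0, min(vm), max(vm),
    qs[1], qs[2], qs[3], qs[4], qs[5],
    qs[4] - qs[2], skew, kurt, acf1, zero_cross,
    peak_count, total_power, dom_freq, dom_power, dom_power_frac,
    dom_freq2, spec_entropy, bp_low, bp_high, bp_ratio
  )
  names(out) <- FEATURE_NAMES
  out
}

#' Extract per-window features from a recording
#'
#' Segments a recording into `window_s`-second windows and computes the
#' 25-feature vector on each window's vector magnitude. The window SD
#' (`vm_sd`) is carried in its own column as well, for non-wear detection.
#'
#' @param recording A [raw_recording].
#' @param window_s Window length in seconds (default 15).
#'
#' @return A tibble with one row per window: `subject_id`, `window_index`,
#'   `window_start`, and the 25 feature columns. The `vm_sd` column (feature
#'   2) is the per-window vector-magnitude SD used by [detect_nonwear()].
#' @export
extract_features <- function(recording, window_s = 15) {
  wins <- segment_windows(recording, window_s = window_s)
  if (nrow(wins) == 0) {
    out <- tibble::as_tibble(matrix(numeric(), 0, length(FEATURE_NAMES),
      dimnames = list(NULL, FEATURE_NAMES)
    ))
    return(dplyr::bind_cols(wins[c("subject_id", "window_index", "window_start")], out))
  }
  feats <- purrr::map(wins$samples, function(d) {
    window_features(vector_magnitude(d), recording$sample_rate, window_s)
  })
  feats <- tibble::as_tibble(do.call(rbind, feats))
  dplyr::bind_cols(
    wins[c("subject_id", "window_index", "window_start")],
    feats
  )
}
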