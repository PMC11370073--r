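# Synthetic raw-signal generator. Hip-accelerometer recordings are emulated as
# gravity baseline + per-axis Gaussian noise + sinusoidal locomotion
# component + Bernoulli high-amplitude bursts, parameterised per activity
# class. Non-wear is emitted as exactly zero-variance gravity-level signal so
# downstream detectors have unambiguous ground truth.

#' Signal parameters for one activity class
#'
#' @param class_label One of `activity_classes()`.
#' @param base_level Gravity-dominated baseline of the vertical axis, in g.
#' @param noise_sd Per-axis Gaussian noise SD, in g.
#' @param oscillation_freq Locomotion frequency in Hz (0 for no oscillation).
#' @param oscillation_amp Amplitude of the sinusoidal component, in g.
#' @param burstiness Fraction in `[0, 1]` of 1-second blocks in which the
#'   oscillation amplitude is multiplied by `burst_mult` — models the
#'   intermittent structure of moderate-vigorous activities and games.
#' @param burst_mult Amplitude multiplier applied in burst blocks.
#'
#' @return A list of class `signal_class_params`.
#' @export
signal_class_params <- function(class_label,
                                base_level = 1.0,
                                noise_sd = 0.02,
                                oscillation_freq = 0,
                                oscillation_amp = 0,
                                burstiness = 0,
                                burst_mult = 2.5) {
  class_label <- match.arg(class_label, ACTIVITY_CLASSES)
  if (noise_sd < 0) abort_arg("noise_sd must be >= 0.")
  if (oscillation_freq < 0) abort_arg("oscillation_freq must be >= 0.")
  if (burstiness < 0 || burstiness > 1) abort_arg("burstiness must be in [0, 1].")
  structure(
    list(
      class_label = class_label, base_level = base_level, noise_sd = noise_sd,
      oscillation_freq = oscillation_freq, oscillation_amp = oscillation_amp,
      burstiness = burstiness, burst_mult = burst_mult
    ),
    class = "signal_class_params"
  )
}

#' Default per-class signal parameters
#'
#' Defaults are ordered so the expected window vector-magnitude SD satisfies
#' SED < L_ACT_G < WALK < MV_ACT_G <= RUN, and sedentary wear stays above
#' the 13 mg non-wear threshold.
#'
#' @return Named list of [signal_class_params()] for the five classes.
#' @export
default_class_params <- function() {
  list(
    SED = signal_class_params("SED", noise_sd = 0.02),
    L_ACT_G = signal_class_params("L_ACT_G",
      noise_sd = 0.08, oscillation_freq = 0.7, oscillation_amp = 0.18
    ),
    MV_ACT_G = signal_class_params("MV_ACT_G",
      noise_sd = 0.12, oscillation_freq = 1.3, oscillation_amp = 0.35,
      burstiness = 0.5
    ),
    WALK = signal_class_params("WALK",
      noise_sd = 0.10, oscillation_freq = 2.0, oscillation_amp = 0.45
    ),
    RUN = signal_class_params("RUN",
      noise_sd = 0.15, oscillation_freq = 3.0, oscillation_amp = 0.90
    )
  )
}

# Unseeded core: caller manages RNG state.
simulate_signal_core <- function(params, duration_s, sample_rate) {
  n <- as.integer(round(duration_s * sample_rate))
  t <- (seq_len(n) - 1) / sample_rate
  osc <- if (params$oscillation_freq > 0 && params$oscillation_amp > 0) {
    a <- params$oscillation_amp * sin(2 * pi * params$oscillation_freq * t)
    if (params$burstiness > 0) {
      n_blocks <- ceiling(duration_s)
      burst <- rbinom(n_blocks, 1, params$burstiness)
      mult <- ifelse(burst[pmin(floor(t) + 1, n_blocks)] == 1, params$burst_mult, 1)
      a * mult
    } else {
      a
    }
  } else {
    rep(0, n)
  }
  if (params$noise_sd > 0) {
    tibble::tibble(
      x = rnorm(n, 0, params$noise_sd),
      y = rnorm(n, 0, params$noise_sd),
      z = params$base_level + osc + rnorm(n, 0, params$noise_sd)
    )
  } else {
    tibble::tibble(x = rep(0, n), y = rep(0, n), z = params$base_level + osc)
  }
}

#' Simulate a tri-axial signal for one activity class
#'
#' @param params A [signal_class_params()].
#' @param duration_s Duration in seconds (> 0).
#' @param sample_rate Sampling frequency in Hz (> 0).
#' @param seed Integer seed; identical seeds reproduce identical samples.
#'
#' @return Tibble with `duration_s * sample_rate` rows and columns `x`,
#'   `y`, `z` in g.
#' @export
simulate_window_signal <- function(params, duration_s, sample_rate = 30, seed = 1) {
  stopifnot(inherits(params, "signal_class_params"))
  if (duration_s <= 0) abort_arg("duration_s must be > 0.")
  if (sample_rate <= 0) abort_arg("sample_rate must be > 0.")
  if (params$oscillation_freq >= sample_rate / 2) {
    abort_arg("oscillation_freq must be below the Nyquist frequency.")
  }
  withr::with_seed(seed, simulate_signal_core(params, duration_s, sample_rate))
}

#' Simulate an annotated training corpus
#'
#' Emulates a labelled corpus of free-living play sessions: each of
#' `n_subjects` children contributes `session_s / 15` fifteen-second windows
#' whose true class is drawn from `class_mix`; per-subject lognormal
#' perturbations of amplitude and noise induce realistic between-child
#' variation, which is what makes leave-one-subject-out validation
#' informative. Defaults (31 subjects, 1200-s sessions) give roughly 2,500
#' labelled windows.
#'
#' @param n_subjects Number of children (>= 2; subject-level cross-validation
#'   needs at least two).
#' @param session_s Session length per child, in seconds.
#' @param class_mix Named probability vector over `activity_classes()`.
#' @param sample_rate Hz.
#' @param seed Integer seed.
#' @param class_params Per-class signal parameters
#'   (default [default_class_params()]).
#' @param subject_sd SD of the log-normal per-subject amplitude/noise
#'   factors (0 disables between-subject variation).
#' @param window_s Window length in seconds.
#'
#' @return Tibble with one row per labelled window: `subject_id`,
#'   `window_index`, `label` (factor over the five classes) and the 25
#'   feature columns.
#' @export
simulate_annotated_corpus <- function(n_subjects = 31,
                                      session_s = 1200,
                                      class_mix = c(
                                        SED = 0.35, L_ACT_G = 0.30,
                                        MV_ACT_G = 0.10, WALK = 0.15, RUN = 0.10
                                      ),
                                      sample_rate = 30,
                                      seed = 1,
                                      class_params = default_class_params(),
                                      subject_sd = 0.08,
                                      window_s = 15) {
  if (n_subjects < 2) abort_arg("n_subjects must be >= 2.")
  if (is.null(names(class_mix)) || !all(names(class_mix) %in% ACTIVITY_CLASSES)) {
    abort_arg("class_mix must be named with activity class labels.")
  }
  class_mix <- class_mix / sum(class_mix)
  n_win <- floor(session_s / window_s)
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_subjects), function(s) {
      amp_f <- exp(rnorm(1, 0, subject_sd))
      noise_f <- exp(rnorm(1, 0, subject_sd))
      labels <- sample(names(class_mix), n_win, replace = TRUE, prob = class_mix)
      feats <- purrr::map(labels, function(lb) {
        p <- class_params[[lb]]
        p$oscillation_amp <- p$oscillation_amp * amp_f
        p$noise_sd <- p$noise_sd * noise_f
        d <- simulate_signal_core(p, window_s, sample_rate)
        window_features(vector_magnitude(d), sample_rate, window_s)
      })
      dplyr::bind_cols(
        tibble::tibble(
          subject_id = sprintf("S%02d", s),
          window_index = seq_len(n_win) - 1L,
          label = activity_factor(labels)
        ),
        tibble::as_tibble(do.call(rbind, feats))
      )
    })
  })
}

#' Simulate a multi-day recording with ground-truth bouts
#'
#' Builds one continuous raw recording from a plan of activity bouts.
#' `NONWEAR` bouts are emitted as exactly zero-variance gravity-level signal
#' (device off-body), giving unambiguous ground truth for non-wear
#' detection. A bout log with the exact start and end of every segment is
#' returned alongside the recording.
#'
#' @param day_plan Data frame with columns `activity` (an activity class or
#'   `"NONWEAR"`) and `duration_s` (> 0), in chronological order.
#' @param sample_rate Hz.
#' @param start_time `POSIXct` start of the recording.
#' @param seed Integer seed.
#' @param subject_id Subject identifier.
#' @param class_params Per-class signal parameters.
#'
#' @return List with `recording` (a [raw_recording]) and `bout_log` (tibble
#'   `activity`, `start`, `end`).
#' @export
simulate_recording <- function(day_plan,
                               sample_rate = 30,
                               start_time = as.POSIXct("2019-05-06 08:00:00", tz = "UTC"),
                               seed = 1,
                               subject_id = "S01",
                               class_params = default_class_params()) {
  if (!is.data.frame(day_plan) || nrow(day_plan) == 0) {
    abort_arg("day_plan must be a non-empty data frame (activity, duration_s).")
  }
  if (!all(c("activity", "duration_s") %in% names(day_plan))) {
    abort_arg("day_plan needs columns `activity` and `duration_s`.")
  }
  if (any(day_plan$duration_s <= 0)) abort_arg("bout durations must be positive.")
  bad <- setdiff(unique(day_plan$activity), c(ACTIVITY_CLASSES, "NONWEAR"))
  if (length(bad) > 0) {
    abort_arg(paste0("unknown activities in plan: ", paste(bad, collapse = ", ")))
  }
  if (!inherits(start_time, "POSIXct")) start_time <- as.POSIXct(start_time, tz = "UTC")

  segs <- withr::with_seed(seed, purrr::map(seq_len(nrow(day_plan)), function(i) {
    act <- day_plan$activity[i]
    dur <- day_plan$duration_s[i]
    if (act == "NONWEAR") {
      n <- as.integer(round(dur * sample_rate))
      tibble::tibble(x = rep(0, n), y = rep(0, n), z = rep(1, n))
    } else {
      simulate_signal_core(class_params[[act]], dur, sample_rate)
    }
  }))
  ends <- cumsum(day_plan$duration_s)
  starts <- c(0, head(ends, -1))
  list(
    recording = raw_recording(
      dplyr::bind_rows(segs), subject_id, start_time, sample_rate
    ),
    bout_log = tibble::tibble(
      activity = day_plan$activity,
      start = start_time + starts,
      end = start_time + ends
    )
  )
}
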