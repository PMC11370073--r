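# Non-wear detection, daily summarisation and inclusion rules.
#
# Non-wear: maximal runs of consecutive 15-s windows whose vector-magnitude
# SD is below 13 mg (0.013 g), spanning at least 30 consecutive minutes.
# Valid day: >= 480 wear minutes. Valid subject-wave: >= 4 valid days
# including >= 1 valid weekend day.

#' Detect non-wear intervals from per-window SDs
#'
#' Scans the ordered per-window vector-magnitude SDs for maximal runs of
#' consecutive windows with `vm_sd < sd_threshold`; runs spanning at least
#' `min_duration_min` become non-wear intervals (the duration bound is
#' inclusive: at 15-s windows, 120 consecutive sub-threshold windows are
#' non-wear, 119 are not). Shorter quiet runs count as wear.
#'
#' @param windows Either a data frame with a `vm_sd` column (and optionally
#'   `window_start`, used to attach datetimes), or a bare numeric vector of
#'   per-window SDs in g. Windows must be contiguous and in time order.
#' @param window_s Window length in seconds (default 15).
#' @param sd_threshold Non-wear SD threshold in g (default 0.013, i.e. 13 mg).
#' @param min_duration_min Minimum run span in minutes (default 30).
#'
#' @return Tibble of intervals: `start_window`, `end_window` (0-based,
#'   inclusive), `n_windows`, `duration_min`, and `start`/`end` datetimes
#'   when `window_start` is available (end is exclusive). Zero rows when no
#'   run qualifies.
#' @export
detect_nonwear <- function(windows, window_s = 15, sd_threshold = 0.013,
                           min_duration_min = 30) {
  if (is.data.frame(windows)) {
    if (!"vm_sd" %in% names(windows)) abort_arg("windows must have a vm_sd column.")
    sds <- windows$vm_sd
    starts <- if ("window_start" %in% names(windows)) windows$window_start else NULL
  } else {
    sds <- as.numeric(windows)
    starts <- NULL
  }
  empty <- tibble::tibble(
    start_window = integer(), end_window = integer(),
    n_windows = integer(), duration_min = numeric()
  )
  if (!is.null(starts)) {
    empty$start <- as.POSIXct(character(), tz = "UTC")
    empty$end <- as.POSIXct(character(), tz = "UTC")
  }
  if (length(sds) == 0) {
    return(empty)
  }
  r <- rle(sds < sd_threshold)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- r$values & (r$lengths * window_s >= min_duration_min * 60)
  if (!any(keep)) {
    return(empty)
  }
  out <- tibble::tibble(
    start_window = run_start[keep] - 1L,
    end_window = run_end[keep] - 1L,
    n_windows = r$lengths[keep],
    duration_min = r$lengths[keep] * window_s / 60
  )
  if (!is.null(starts)) {
    out$start <- starts[out$start_window + 1L]
    out$end <- starts[out$end_window + 1L] + window_s
  }
  out
}

window_in_nonwear <- function(window_start, nonwear) {
  if (is.null(nonwear) || nrow(nonwear) == 0) {
    return(rep(FALSE, length(window_start)))
  }
  if (!all(c("start", "end") %in% names(nonwear))) {
    abort_arg("nonwear intervals need start/end datetimes.")
  }
  out <- rep(FALSE, length(window_start))
  for (i in seq_len(nrow(nonwear))) {
    out <- out | (window_start >= nonwear$start[i] & window_start < nonwear$end[i])
  }
  out
}

#' Summarise one calendar day of classified windows
#'
#' Aggregates per-window activity classes into daily behaviour minutes.
#' Windows inside non-wear intervals are excluded from all behaviour
#' minutes and from wear time. Minutes are window counts times
#' `window_s / 60` (0.25 min at 15-s windows). Energetic play is the sum of
#' walking, running and moderate-vigorous activities and games; total
#' physical activity is energetic play plus light-intensity activities and
#' games; a day is valid when wear time is at least `wear_threshold_min`.
#'
#' @param windows Data frame of one calendar day's windows: `window_start`
#'   (`POSIXct`), `class` (activity class labels) and optionally
#'   `subject_id`.
#' @param nonwear Non-wear intervals with `start`/`end` datetimes (e.g. from
#'   [detect_nonwear()]), or `NULL`.
#' @param window_s Window length in seconds.
#' @param wear_threshold_min Valid-day wear threshold in minutes (default 480).
#'
#' @return One-row tibble: `subject_id`, `date`, `sedentary`, `lpa`,
#'   `walk`, `run`, `mv_act_g`, `energetic_play`, `total_pa`,
#'   `wear_minutes`, `nonwear_minutes`, `is_weekend`, `is_valid`.
#' @export
summarize_day <- function(windows, nonwear = NULL, window_s = 15,
                          wear_threshold_min = 480) {
  if (!all(c("window_start", "class") %in% names(windows))) {
    abort_arg("windows need `window_start` and `class` columns.")
  }
  dates <- unique(as.Date(windows$window_start))
  if (length(dates) != 1) {
    abort_arg("windows span more than one calendar day; split days first.")
  }
  cls <- activity_factor(windows$class)
  if (anyNA(cls)) abort_arg("unknown class labels in windows.")
  nw <- window_in_nonwear(windows$window_start, nonwear)
  worn <- cls[!nw]
  mins <- function(lbl) sum(worn == lbl) * window_s / 60
  sed <- mins("SED"); lpa <- mins("L_ACT_G")
  walk <- mins("WALK"); run <- mins("RUN"); mv <- mins("MV_ACT_G")
  ep <- walk + run + mv
  wear <- sed + lpa + ep
  tibble::tibble(
    subject_id = if ("subject_id" %in% names(windows)) windows$subject_id[1] else NA_character_,
    date = dates,
    sedentary = sed, lpa = lpa, walk = walk, run = run, mv_act_g = mv,
    energetic_play = ep, total_pa = lpa + ep,
    wear_minutes = wear,
    nonwear_minutes = sum(nw) * window_s / 60,
    is_weekend = format(dates, "%u") %in% c("6", "7"),
    is_valid = wear >= wear_threshold_min
  )
}

#' Summarise a multi-day window stream into daily summaries
#'
#' Splits classified windows at local calendar midnight (non-wear runs are
#' detected first and clipped at midnight, so a run bridging midnight counts
#' toward both days) and applies [summarize_day()] to each day.
#'
#' @inheritParams summarize_day
#' @return Tibble with one row per subject-day.
#' @export
summarize_days <- function(windows, nonwear = NULL, window_s = 15,
                           wear_threshold_min = 480) {
  keys <- tibble::tibble(
    subject_id = if ("subject_id" %in% names(windows)) windows$subject_id else NA_character_,
    date = as.Date(windows$window_start)
  )
  split_idx <- split(seq_len(nrow(windows)), keys, drop = TRUE)
  purrr::map_dfr(split_idx, function(idx) {
    summarize_day(windows[idx, , drop = FALSE],
      nonwear = nonwear,
      window_s = window_s, wear_threshold_min = wear_threshold_min
    )
  })
}

#' Apply the valid-subject inclusion rule
#'
#' A subject-wave is included when it has at least `min_days` valid
#' monitoring days of which at least `min_weekend` are valid weekend days.
#'
#' @param summaries Daily summaries (rows with `subject_id`, `is_valid`,
#'   `is_weekend`; an optional `wave` column groups waves separately).
#' @param min_days Minimum number of valid days (default 4).
#' @param min_weekend Minimum number of valid weekend days (default 1).
#'
#' @return Tibble with one row per subject(-wave): `n_valid_days`,
#'   `n_valid_weekend`, `include`.
#' @export
select_valid_subjects <- function(summaries, min_days = 4, min_weekend = 1) {
  if (!all(c("subject_id", "is_valid", "is_weekend") %in% names(summaries))) {
    abort_arg("summaries need subject_id, is_valid, is_weekend columns.")
  }
  keys <- if ("wave" %in% names(summaries)) c("subject_id", "wave") else "subject_id"
  summaries |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_valid_days = sum(.data$is_valid),
      n_valid_weekend = sum(.data$is_valid & .data$is_weekend),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      include = .data$n_valid_days >= min_days & .data$n_valid_weekend >= min_weekend
    )
}
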