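# Age-specific 24-hour movement guideline scoring (physical-activity
# components): toddlers need >= 180 min/day total physical activity;
# preschoolers (3-5 y) additionally need >= 60 min/day of energetic play;
# school-aged children need >= 60 min/day of energetic play (MVPA). All
# thresholds are inclusive.

GUIDELINE_RULES <- tibble::tibble(
  rule_id = c("EY_TODDLER", "EY_PRESCHOOL", "CYP_SCHOOL"),
  tpa_min = c(180, 180, NA_real_),
  mvpa_min = c(NA_real_, 60, 60)
)

#' The guideline rule table
#'
#' @return Tibble with `rule_id`, `tpa_min` (min/day total physical
#'   activity, `NA` if the rule has no TPA term) and `mvpa_min` (min/day
#'   energetic play, `NA` if none).
#' @export
guideline_rules <- function() GUIDELINE_RULES

#' Assign the age-appropriate guideline rule
#'
#' School-aged children (by enrolment status, not age — five-year-olds
#' already at school are scored against the school-age rule) get
#' `CYP_SCHOOL`; otherwise children under three get `EY_TODDLER` and three-
#' to-five-year-olds get `EY_PRESCHOOL`.
#'
#' @param age_years Decimal age(s) in years, within `[1.5, 8]`.
#' @param school_status Logical: attending full-time school.
#'
#' @return Character vector of rule ids.
#' @export
#'
#' @examples
#' assign_rule(c(2.4, 4.0, 5.2), c(FALSE, FALSE, TRUE))
assign_rule <- function(age_years, school_status) {
  if (any(!is.finite(age_years)) || any(age_years < 1.5 | age_years > 8)) {
    abort_arg("age_years must be within [1.5, 8].")
  }
  n <- max(length(age_years), length(school_status))
  age_years <- rep_len(age_years, n)
  school_status <- rep_len(as.logical(school_status), n)
  ifelse(school_status, "CYP_SCHOOL",
    ifelse(age_years < 3, "EY_TODDLER", "EY_PRESCHOOL")
  )
}

#' Per-child mean daily behaviours over valid days
#'
#' Unweighted arithmetic means of the behaviour columns over valid days,
#' per subject (and wave, when present).
#'
#' @param summaries Daily summaries (see [summarize_day()]); only rows with
#'   `is_valid` contribute.
#'
#' @return Tibble with one row per subject(-wave): `n_valid_days` and
#'   `mean_`-prefixed behaviour columns (`mean_tpa`, `mean_mvpa`,
#'   `mean_sedentary`, `mean_lpa`, `mean_walk`, `mean_run`,
#'   `mean_mv_act_g`, `mean_wear`).
#' @export
mean_daily_behaviours <- function(summaries) {
  valid <- summaries[summaries$is_valid, , drop = FALSE]
  if (nrow(valid) == 0) abort_arg("no valid days to average.")
  keys <- if ("wave" %in% names(summaries)) c("subject_id", "wave") else "subject_id"
  valid |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_valid_days = dplyr::n(),
      mean_tpa = mean(.data$total_pa),
      mean_mvpa = mean(.data$energetic_play),
      mean_sedentary = mean(.data$sedentary),
      mean_lpa = mean(.data$lpa),
      mean_walk = mean(.data$walk),
      mean_run = mean(.data$run),
      mean_mv_act_g = mean(.data$mv_act_g),
      mean_wear = mean(.data$wear_minutes),
      .groups = "drop"
    )
}

rule_met <- function(rule_id, tpa, mvpa) {
  r <- GUIDELINE_RULES[match(rule_id, GUIDELINE_RULES$rule_id), ]
  (is.na(r$tpa_min) | tpa >= r$tpa_min) & (is.na(r$mvpa_min) | mvpa >= r$mvpa_min)
}

#' Score guideline adherence
#'
#' Applies the assigned rule to each child's physical-activity summary.
#' By default adherence is judged on the mean across valid days (one
#' child-level binary, the quantity modelled by the logistic trajectory
#' model); `method = "every_day"` instead requires every valid day to meet
#' the rule individually — for that method supply the daily `summaries`.
#'
#' @param means Per-child means from [mean_daily_behaviours()], with added
#'   columns `age_years` and `school_status` (or an explicit `rule_id`).
#' @param method `"mean"` (default) or `"every_day"`.
#' @param summaries Daily summaries; required for `method = "every_day"`.
#'
#' @return `means` with columns `rule_id` and `meets` appended.
#' @export
meets_guideline <- function(means, method = c("mean", "every_day"), summaries = NULL) {
  method <- match.arg(method)
  if (!"rule_id" %in% names(means)) {
    if (!all(c("age_years", "school_status") %in% names(means))) {
      abort_arg("supply rule_id, or age_years + school_status.")
    }
    means$rule_id <- assign_rule(means$age_years, means$school_status)
  }
  bad <- setdiff(unique(means$rule_id), GUIDELINE_RULES$rule_id)
  if (length(bad) > 0) abort_arg(paste0("unknown rule_id: ", paste(bad, collapse = ", ")))
  if (method == "mean") {
    means$meets <- rule_met(means$rule_id, means$mean_tpa, means$mean_mvpa)
    return(means)
  }
  if (is.null(summaries)) abort_arg("method = 'every_day' needs `summaries`.")
  keys <- intersect(c("subject_id", "wave"), names(means))
  daily <- summaries[summaries$is_valid, , drop = FALSE] |>
    dplyr::left_join(means[c(keys, "rule_id")], by = keys) |>
    dplyr::mutate(day_meets = rule_met(.data$rule_id, .data$total_pa, .data$energetic_play)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(meets = all(.data$day_meets), .groups = "drop")
  dplyr::left_join(means, daily, by = keys)
}

#' Energetic-play deficit relative to the recommendation
#'
#' Minutes of additional daily energetic play needed to reach the
#' recommendation; zero when the recommendation is already met.
#'
#' @param mean_mvpa Mean daily energetic play, min/day (>= 0).
#' @param recommendation Recommended minimum, min/day (default 60).
#'
#' @return `pmax(0, recommendation - mean_mvpa)`.
#' @export
#'
#' @examples
#' energetic_play_deficit(35.2) # 24.8 min/day short of the 60-min target
energetic_play_deficit <- function(mean_mvpa, recommendation = 60) {
  if (any(mean_mvpa < 0)) abort_arg("mean_mvpa must be >= 0.")
  pmax(0, recommendation - mean_mvpa)
}

#' Aggregate adherence report by age and sex
#'
#' @param adherence Output of [meets_guideline()] with `age_years` and
#'   `sex` columns.
#'
#' @return Tibble: `age` (integer years), `sex`, `n`, `n_meeting`,
#'   `pct_meeting`.
#' @export
adherence_report <- function(adherence) {
  adherence |>
    dplyr::mutate(age = floor(.data$age_years)) |>
    dplyr::group_by(.data$age, .data$sex) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_meeting = sum(.data$meets),
      pct_meeting = 100 * mean(.data$meets),
      .groups = "drop"
    )
}
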