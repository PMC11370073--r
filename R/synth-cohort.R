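# Two-wave cohort generator: day-level movement-behaviour summaries with
# known spline-shaped age effects, sex effects, random child intercepts and
# residual noise — the parameter-recovery surface for the trajectory models.

#' Default true trajectory curves
#'
#' Smooth mean curves (min/day as functions of age in years) used by the
#' cohort generator: total physical activity peaks near age five then
#' declines, energetic play rises monotonically, and sedentary time is
#' U-shaped with its minimum near five. Each curve is a restricted-cubic-
#' spline interpolant on the canonical knots for the requested age range, so
#' the generator's truth lies exactly in the function space of the
#' trajectory models fitted with the same knots.
#'
#' @param age_range Length-2 numeric, default `c(2, 7)`.
#'
#' @return List with `curves` (named list of functions of age:
#'   `total_pa`, `energetic_play`, `sedentary`) and `spec` (the
#'   [rcs_spec()] the curves are built on).
#' @export
default_true_curves <- function(age_range = c(2, 7)) {
  # canonical Harrell knots for a uniform age distribution on age_range
  q <- c(0.05, 0.35, 0.65, 0.95)
  spec <- rcs_spec(age_range[1] + q * diff(age_range))
  a <- age_range[1] + c(0, 0.3, 0.6, 1) * diff(age_range) # anchor ages
  list(
    curves = list(
      total_pa = rcs_interpolant(a, c(340, 372, 385, 362), spec),
      energetic_play = rcs_interpolant(a, c(32, 41, 50, 62), spec),
      sedentary = rcs_interpolant(a, c(385, 360, 345, 363), spec)
    ),
    spec = spec
  )
}

OUTCOMES <- c("total_pa", "energetic_play", "sedentary")

#' Cohort simulation parameters
#'
#' @param n_children Number of children enrolled at wave 1.
#' @param sex_ratio Fraction male.
#' @param age_range Study age range in years, default `c(2, 7)`: wave-1 ages
#'   are uniform on `[age_range[1], age_range[2] - wave_gap]`, wave-2 age is
#'   wave-1 age plus `wave_gap`.
#' @param true_curves Named list of mean functions of age for `total_pa`,
#'   `energetic_play` and `sedentary` (min/day); default
#'   [default_true_curves()].
#' @param sex_offsets Named numeric: additive offsets for boys (min/day).
#' @param random_intercept_sd,residual_sd Scalar or per-outcome named
#'   numeric (min/day). A scalar is applied to every outcome.
#' @param attrition_wave2 Fraction of children lost before wave 2.
#' @param wave_gap Years between waves.
#' @param days_range Integer range of monitored days per child-wave.
#' @param seed Integer seed.
#'
#' @return List of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_children = 1000,
                              sex_ratio = 0.515,
                              age_range = c(2, 7),
                              true_curves = NULL,
                              sex_offsets = c(
                                total_pa = 10, energetic_play = 5,
                                sedentary = -8
                              ),
                              random_intercept_sd = c(
                                total_pa = 20, energetic_play = 8,
                                sedentary = 20
                              ),
                              residual_sd = c(
                                total_pa = 30, energetic_play = 12,
                                sedentary = 30
                              ),
                              attrition_wave2 = 0.6,
                              wave_gap = 2.4,
                              days_range = c(4, 7),
                              seed = 1) {
  if (sex_ratio < 0 || sex_ratio > 1) abort_arg("sex_ratio must be in [0, 1].")
  if (attrition_wave2 < 0 || attrition_wave2 > 1) {
    abort_arg("attrition_wave2 must be in [0, 1].")
  }
  expand <- function(x, what, nonneg = FALSE) {
    if (length(x) == 1 && is.null(names(x))) x <- setNames(rep(x, 3), OUTCOMES)
    if (!all(OUTCOMES %in% names(x))) {
      abort_arg(paste0(what, " must be a scalar or named over ", paste(OUTCOMES, collapse = ", ")))
    }
    if (nonneg && any(x[OUTCOMES] < 0)) abort_arg(paste0(what, " must be >= 0."))
    x[OUTCOMES]
  }
  if (is.null(true_curves)) true_curves <- default_true_curves(age_range)$curves
  if (!all(OUTCOMES %in% names(true_curves))) {
    abort_arg("true_curves must contain total_pa, energetic_play, sedentary.")
  }
  grid <- seq(age_range[1], age_range[2], length.out = 26)
  for (o in OUTCOMES) {
    if (any(true_curves[[o]](grid) <= 0)) {
      abort_arg(paste0("true curve for ", o, " must be positive over the age range."))
    }
  }
  structure(
    list(
      n_children = n_children, sex_ratio = sex_ratio, age_range = age_range,
      true_curves = true_curves,
      sex_offsets = expand(sex_offsets, "sex_offsets"),
      random_intercept_sd = expand(random_intercept_sd, "random_intercept_sd", nonneg = TRUE),
      residual_sd = expand(residual_sd, "residual_sd", nonneg = TRUE),
      attrition_wave2 = attrition_wave2, wave_gap = wave_gap,
      days_range = days_range, seed = seed
    ),
    class = "cohort_sim_params"
  )
}

# Fixed split of energetic play into walking / running / moderate-vigorous
# activities and games (fractions sum to 1, so component sums are exact).
EP_SPLIT <- c(walk = 0.44, run = 0.11, mv_act_g = 0.45)

#' Simulate a two-wave cohort of day-level summaries
#'
#' Each retained child contributes 4-7 monitored days per wave. A day's
#' value for each outcome is `true_curve(age) + sex_offset * male +
#' child_intercept + residual`; light-intensity activity is total PA minus
#' energetic play, wear time is sedentary + total PA (so behaviour minutes
#' and wear time are conserved exactly), and energetic play is split into
#' walking, running and moderate-vigorous components in fixed proportions.
#' Child-level covariates (maternal work status, dwelling type, yard size)
#' and wave-level context (season from the monitoring dates; a COVID-period
#' flag at wave 2) are generated alongside.
#'
#' @param params A [cohort_sim_params()].
#'
#' @return List of class `simulated_cohort`: `days` (one row per monitored
#'   day, with ages, covariates and all behaviour columns), `children`
#'   (one row per child) and `truth` (the generating parameters).
#' @export
simulate_cohort <- function(params = cohort_sim_params()) {
  stopifnot(inherits(params, "cohort_sim_params"))
  p <- params
  withr::with_seed(p$seed, {
    n <- p$n_children
    children <- tibble::tibble(
      child_id = sprintf("C%04d", seq_len(n)),
      sex = factor(
        ifelse(runif(n) < p$sex_ratio, "male", "female"),
        levels = c("female", "male")
      ),
      age_wave1 = runif(n, p$age_range[1], p$age_range[2] - p$wave_gap),
      maternal_work = factor(
        ifelse(runif(n) < 0.81, "working", "not_working"),
        levels = c("working", "not_working")
      ),
      dwelling = factor(
        ifelse(runif(n) < 0.85, "house", "other"),
        levels = c("house", "other")
      ),
      yard = factor(
        ifelse(runif(n) < 0.80, "medium_large", "none_small"),
        levels = c("medium_large", "none_small")
      ),
      retained_wave2 = runif(n) >= p$attrition_wave2
    )

    intercepts <- purrr::map(OUTCOMES, function(o) {
      rnorm(n, 0, p$random_intercept_sd[[o]])
    })
    names(intercepts) <- OUTCOMES

    one_wave <- function(wave, ids) {
      if (length(ids) == 0) {
        return(tibble::tibble())
      }
      base_year <- if (wave == 1) 2019 else 2021
      purrr::map_dfr(ids, function(i) {
        n_days <- sample(seq(p$days_range[1], p$days_range[2]), 1)
        start <- as.Date(sprintf("%d-01-01", base_year)) + sample.int(358, 1)
        dates <- start + seq_len(n_days) - 1
        age <- children$age_wave1[i] + if (wave == 2) p$wave_gap else 0
        male <- children$sex[i] == "male"
        vals <- purrr::map(OUTCOMES, function(o) {
          p$true_curves[[o]](age) + p$sex_offsets[[o]] * male +
            intercepts[[o]][i] + rnorm(n_days, 0, p$residual_sd[[o]])
        })
        names(vals) <- OUTCOMES
        ep <- vals$energetic_play
        tibble::tibble(
          child_id = children$child_id[i],
          wave = wave,
          age_years = age,
          date = dates,
          sedentary = vals$sedentary,
          lpa = vals$total_pa - ep,
          walk = EP_SPLIT[["walk"]] * ep,
          run = EP_SPLIT[["run"]] * ep,
          mv_act_g = EP_SPLIT[["mv_act_g"]] * ep,
          energetic_play = ep,
          total_pa = vals$total_pa,
          wear_minutes = vals$sedentary + vals$total_pa
        )
      })
    }

    days <- dplyr::bind_rows(
      one_wave(1, seq_len(n)),
      one_wave(2, which(children$retained_wave2))
    )
    month <- as.integer(format(days$date, "%m"))
    days <- days |>
      dplyr::mutate(
        is_weekend = format(.data$date, "%u") %in% c("6", "7"),
        is_valid = .data$wear_minutes >= 480,
        season = factor(
          c(
            "summer", "summer", "autumn", "autumn", "autumn", "winter",
            "winter", "winter", "spring", "spring", "spring", "summer"
          )[month],
          levels = c("summer", "autumn", "winter", "spring")
        ),
        covid = .data$wave == 2 & .data$date >= as.Date("2020-03-15")
      ) |>
      dplyr::left_join(
        children[c("child_id", "sex", "maternal_work", "dwelling", "yard")],
        by = "child_id"
      ) |>
      dplyr::relocate("sex", .after = "age_years")

    structure(
      list(days = days, children = children, truth = p),
      class = "simulated_cohort"
    )
  })
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf(
    "<simulated_cohort> %d children, %d monitored days (%d wave-2 children)\n",
    nrow(x$children), nrow(x$days), sum(x$children$retained_wave2)
  ))
  invisible(x)
}

#' Simulate child-wave guideline adherence with a known logit model
#'
#' Generates one binary adherence outcome per child-wave with
#' `logit P(meets) = beta0 + beta_age * age + child_intercept` — a small,
#' fully known surface for checking logistic trajectory models.
#'
#' @param n_children Number of children.
#' @param beta0,beta_age True intercept and age slope on the logit scale.
#' @param intercept_sd SD of the child random intercept (logit scale).
#' @param age_range,wave_gap,attrition_wave2 As in [cohort_sim_params()].
#' @param seed Integer seed.
#'
#' @return List with `data` (tibble `child_id`, `wave`, `age_years`, `sex`,
#'   `meets`) and `truth`.
#' @export
simulate_adherence_cohort <- function(n_children = 800,
                                      beta0 = -3,
                                      beta_age = 0.7,
                                      intercept_sd = 1,
                                      age_range = c(2, 7),
                                      wave_gap = 2.4,
                                      attrition_wave2 = 0.4,
                                      seed = 1) {
  withr::with_seed(seed, {
    n <- n_children
    b <- rnorm(n, 0, intercept_sd)
    age1 <- runif(n, age_range[1], age_range[2] - wave_gap)
    sex <- factor(
      ifelse(runif(n) < 0.5, "male", "female"),
      levels = c("female", "male")
    )
    keep2 <- runif(n) >= attrition_wave2
    d <- dplyr::bind_rows(
      tibble::tibble(id = seq_len(n), wave = 1, age_years = age1),
      tibble::tibble(id = which(keep2), wave = 2, age_years = age1[keep2] + wave_gap)
    )
    eta <- beta0 + beta_age * d$age_years + b[d$id]
    data <- tibble::tibble(
      child_id = sprintf("C%04d", d$id),
      wave = d$wave,
      age_years = d$age_years,
      sex = sex[d$id],
      meets = rbinom(nrow(d), 1, plogis(eta))
    )
    list(
      data = data,
      truth = list(beta0 = beta0, beta_age = beta_age, intercept_sd = intercept_sd)
    )
  })
}
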