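# End-to-end pipeline: simulate -> features -> classify -> wear/validity ->
# guidelines -> trajectory models -> report. Every artefact is a plain CSV
# or JSON file stamped (via the manifest) with the configuration hash and
# seed; a rerun with the same configuration is byte-identical.

stage_msg <- function(log, ...) {
  line <- sprintf(...)
  message(line)
  c(log, line)
}

#' Random one-day wear protocol
#'
#' Builds a day plan of activity bouts (5-30 min) covering `day_minutes`
#' minutes, with one embedded `nonwear_min`-minute non-wear block at a
#' random position — used by the pipeline's recording simulation.
#'
#' @param day_minutes Total plan length in minutes.
#' @param nonwear_min Embedded non-wear block length in minutes (0 for none).
#'
#' @return Tibble `activity`, `duration_s` (consumes RNG; seed managed by
#'   the caller).
#' @export
random_day_plan <- function(day_minutes = 660, nonwear_min = 45) {
  wear_target <- day_minutes - nonwear_min
  probs <- c(SED = 0.40, L_ACT_G = 0.30, MV_ACT_G = 0.10, WALK = 0.12, RUN = 0.08)
  acts <- character()
  durs <- numeric()
  total <- 0
  while (total < wear_target) {
    d <- min(sample(c(5, 10, 15, 20, 30), 1), wear_target - total)
    acts <- c(acts, sample(names(probs), 1, prob = probs))
    durs <- c(durs, d)
    total <- total + d
  }
  plan <- tibble::tibble(activity = acts, duration_s = durs * 60)
  if (nonwear_min > 0) {
    pos <- sample.int(nrow(plan) + 1, 1)
    nw <- tibble::tibble(activity = "NONWEAR", duration_s = nonwear_min * 60)
    plan <- dplyr::bind_rows(
      plan[seq_len(pos - 1), ], nw,
      plan[seq(pos, length.out = nrow(plan) - pos + 1), ]
    )
  }
  plan
}

#' Run the full pipeline
#'
#' Executes the complete analysis on synthetic inputs: trains and validates
#' the window classifier (leave-one-subject-out), classifies multi-day
#' recordings, applies non-wear and validity rules, scores guideline
#' adherence, fits the spline mixed models on a simulated cohort and writes
#' marginal means — all artefacts as CSV/JSON under `out_dir`.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Output directory (created if needed).
#'
#' @return Invisibly, a list with the artefact paths and key in-memory
#'   results (`loso`, `summaries`, `adherence`, `lmm`, `marginal_means`).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("actikids_run_")) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log <- character()
  log <- stage_msg(log, "pipeline start: config %s, seed %d", hash, config$seed)
  paths <- list(config = file.path(out_dir, "config.yaml"))
  write_config(config, paths$config)

  # -- stage 1: corpus, classifier, LOSO validation ------------------------
  corpus <- simulate_annotated_corpus(
    n_subjects = config$corpus$n_subjects,
    session_s = config$corpus$session_s,
    sample_rate = config$sample_rate,
    window_s = config$window_s,
    seed = config$seed + 1
  )
  log <- stage_msg(
    log, "corpus: %d windows from %d subjects",
    nrow(corpus), config$corpus$n_subjects
  )
  model <- train_activity_model(corpus,
    n_trees = config$classifier$n_trees,
    seed = config$seed + 2
  )
  loso <- loso_cv(corpus, n_trees = config$classifier$n_trees, seed = config$seed + 2)
  log <- stage_msg(log, "LOSO: macro F %.3f over %d windows", loso$macro_f, loso$n)
  paths$loso <- file.path(out_dir, "loso_metrics.json")
  jsonlite::write_json(
    list(
      confusion = loso$confusion, per_class = loso$per_class,
      macro_f = loso$macro_f, accuracy = loso$accuracy, n = loso$n
    ),
    paths$loso,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  # -- stage 2: recordings -> features -> predictions -> daily summaries ---
  rec_cfg <- config$recordings
  first_day <- as.Date("2019-05-02") # Thursday: 5 days span a weekend
  child_ages <- withr::with_seed(
    config$seed + 3,
    runif(rec_cfg$n_children, 3, 5)
  )
  all_win <- list()
  all_nw <- list()
  for (i in seq_len(rec_cfg$n_children)) {
    sid <- sprintf("P%02d", i)
    for (d in seq_len(rec_cfg$n_days)) {
      dseed <- config$seed + 100 + i * 50 + d
      plan <- withr::with_seed(dseed, random_day_plan(rec_cfg$day_minutes))
      sim <- simulate_recording(
        plan,
        sample_rate = config$sample_rate,
        start_time = as.POSIXct(
          paste(first_day + d - 1, "08:00:00"),
          tz = "UTC"
        ),
        seed = dseed + 1, subject_id = sid
      )
      feats <- extract_features(sim$recording, window_s = config$window_s)
      feats$class <- as.character(predict(model, feats))
      nw <- detect_nonwear(feats,
        window_s = config$window_s,
        sd_threshold = config$nonwear$sd_threshold,
        min_duration_min = config$nonwear$min_duration_min
      )
      all_win[[length(all_win) + 1]] <-
        feats[c("subject_id", "window_start", "class", "vm_sd")]
      if (nrow(nw) > 0) all_nw[[length(all_nw) + 1]] <- nw
    }
  }
  windows <- dplyr::bind_rows(all_win)
  windows$intensity <- as.character(map_to_intensity(windows$class))
  nonwear <- dplyr::bind_rows(all_nw)
  log <- stage_msg(
    log, "recordings: %d windows, %d non-wear intervals (%.0f min)",
    nrow(windows), nrow(nonwear), sum(nonwear$duration_min)
  )
  paths$predictions <- file.path(out_dir, "predictions.csv")
  readr::write_csv(windows, paths$predictions)
  paths$nonwear <- file.path(out_dir, "nonwear.csv")
  readr::write_csv(
    nonwear[c("start", "end", "duration_min")] |>
      dplyr::mutate(
        start = format(.data$start, "%Y-%m-%dT%H:%M:%S"),
        end = format(.data$end, "%Y-%m-%dT%H:%M:%S")
      ),
    paths$nonwear
  )

  summaries <- summarize_days(windows,
    nonwear = nonwear, window_s = config$window_s,
    wear_threshold_min = config$valid_day$wear_min
  )
  inclusion <- select_valid_subjects(summaries,
    min_days = config$valid_subject$min_days,
    min_weekend = config$valid_subject$min_weekend
  )
  log <- stage_msg(
    log, "summaries: %d days, %d valid; %d/%d subjects included",
    nrow(summaries), sum(summaries$is_valid),
    sum(inclusion$include), nrow(inclusion)
  )
  paths$daily <- file.path(out_dir, "daily_summaries.csv")
  readr::write_csv(summaries, paths$daily)
  paths$inclusion <- file.path(out_dir, "inclusion.csv")
  readr::write_csv(inclusion, paths$inclusion)

  # -- stage 3: guideline adherence ---------------------------------------
  included <- inclusion$subject_id[inclusion$include]
  adherence <- NULL
  if (length(included) > 0) {
    means <- mean_daily_behaviours(
      summaries[summaries$subject_id %in% included, ]
    )
    means$age_years <- child_ages[as.integer(sub("P", "", means$subject_id))]
    means$school_status <- FALSE
    adherence <- meets_guideline(means)
    adherence$deficit <- energetic_play_deficit(
      adherence$mean_mvpa, config$guidelines$mvpa_min
    )
    paths$adherence <- file.path(out_dir, "adherence.csv")
    readr::write_csv(adherence, paths$adherence)
    log <- stage_msg(
      log, "adherence: %d/%d children meeting",
      sum(adherence$meets), nrow(adherence)
    )
  } else {
    log <- stage_msg(log, "adherence: no subjects met the inclusion rule")
  }

  # -- stage 4: cohort trajectory models ----------------------------------
  cohort <- simulate_cohort(cohort_sim_params(
    n_children = config$cohort$n_children, seed = config$seed + 4
  ))
  days <- cohort$days
  paths$cohort <- file.path(out_dir, "cohort_days.csv")
  readr::write_csv(days, paths$cohort)
  lmm <- fit_trajectory_lmm(days, "total_pa", covariates = config$covariates)
  mm <- marginal_means(lmm,
    ages = config$marginal_means$ages,
    policy = config$marginal_means$policy
  )
  wald <- wald_joint_test(lmm)
  log <- stage_msg(
    log, "LMM total_pa: %d obs, age-by-sex Wald p = %.3f",
    stats::nobs(lmm$model), wald$p.value
  )
  paths$coefficients <- file.path(out_dir, "lmm_coefficients.csv")
  readr::write_csv(generics::tidy(lmm), paths$coefficients)
  paths$marginal_means <- file.path(out_dir, "marginal_means.csv")
  readr::write_csv(tibble::as_tibble(mm), paths$marginal_means)

  # child-wave adherence from the simulated cohort, then the logistic model
  cohort_means <- mean_daily_behaviours(
    dplyr::rename(days, subject_id = "child_id")
  )
  cohort_means <- cohort_means |>
    dplyr::left_join(
      dplyr::distinct(days, .data$child_id, .data$wave,
        age_years = .data$age_years, sex = .data$sex
      ),
      by = c(subject_id = "child_id", wave = "wave")
    ) |>
    dplyr::mutate(school_status = .data$wave == 2)
  cohort_adh <- meets_guideline(cohort_means)
  glmm <- fit_trajectory_glmm(
    dplyr::mutate(dplyr::rename(cohort_adh, child_id = "subject_id"),
      meets = as.integer(.data$meets)
    ),
    "meets"
  )
  report <- adherence_report(cohort_adh)
  paths$adherence_report <- file.path(out_dir, "adherence_report.csv")
  readr::write_csv(report, paths$adherence_report)
  paths$tests <- file.path(out_dir, "model_tests.json")
  jsonlite::write_json(
    list(
      age_by_sex_wald = as.list(wald),
      glmm_degenerate = glmm$degenerate,
      glmm_converged = glmm$converged
    ),
    paths$tests,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  # -- manifest and run log ------------------------------------------------
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(
      config_hash = hash, seed = config$seed,
      counts = list(
        corpus_windows = nrow(corpus),
        recording_windows = nrow(windows),
        nonwear_intervals = nrow(nonwear),
        days = nrow(summaries), valid_days = sum(summaries$is_valid),
        included_subjects = sum(inclusion$include),
        cohort_days = nrow(days)
      )
    ),
    paths$manifest,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  paths$log <- file.path(out_dir, "run_log.txt")
  writeLines(log, paths$log)

  invisible(list(
    paths = paths, loso = loso, summaries = summaries,
    inclusion = inclusion, adherence = adherence,
    lmm = lmm, marginal_means = mm, glmm = glmm
  ))
}
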