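# Synthetic signal, corpus, recording and cohort generators.

test_that("window signals are seeded, sized and centred as specified", {
  p <- default_class_params()
  a <- simulate_window_signal(p$SED, 15, 30, seed = 7)
  b <- simulate_window_signal(p$SED, 15, 30, seed = 7)
  expect_identical(a, b)
  expect_equal(nrow(a), 450)
  c2 <- simulate_window_signal(p$SED, 15, 30, seed = 8)
  expect_false(identical(a, c2))
  expect_error(simulate_window_signal(p$SED, 0, 30), class = "actikids_argument_error")
  expect_error(simulate_window_signal(p$SED, 15, -1), class = "actikids_argument_error")
})

test_that("zero-noise sedentary signal has constant vector magnitude", {
  p <- signal_class_params("SED", noise_sd = 0)
  d <- simulate_window_signal(p, 15, 30, seed = 99)
  vm <- vector_magnitude(d)
  expect_equal(vm, rep(1.0, 450))
  expect_equal(sd(vm), 0)
})

test_that("walking oscillation dominates the spectrum at its true frequency", {
  p <- default_class_params()
  for (s in c(3, 21, 77)) {
    d <- simulate_window_signal(p$WALK, 15, 30, seed = s)
    peak <- dft_peak_freq(vector_magnitude(d), 30)
    expect_lt(abs(peak - 2.0), 1 / 15 + 1e-9) # within one frequency bin
  }
})

test_that("annotated corpus has the right scale, labels and determinism", {
  corp <- simulate_annotated_corpus(n_subjects = 31, session_s = 1200, seed = 1)
  expect_equal(nrow(corp), 31 * 80) # ~2,500 labelled windows at study scale
  expect_equal(length(unique(corp$subject_id)), 31)
  expect_true(all(levels(corp$label) == activity_classes()))

  again <- simulate_annotated_corpus(n_subjects = 31, session_s = 1200, seed = 1)
  expect_identical(corp, again)

  sed_only <- simulate_annotated_corpus(
    n_subjects = 2, session_s = 150,
    class_mix = c(SED = 1), seed = 4
  )
  expect_true(all(sed_only$label == "SED"))
  expect_error(simulate_annotated_corpus(n_subjects = 1), class = "actikids_argument_error")
})

test_that("mean window SD separates the activity classes in order", {
  p <- default_class_params()
  mean_sd <- vapply(activity_classes(), function(cl) {
    sds <- vapply(1:100, function(i) {
      d <- simulate_window_signal(p[[cl]], 15, 30, seed = 1000 + i)
      sd(vector_magnitude(d))
    }, numeric(1))
    mean(sds)
  }, numeric(1))
  expect_lt(mean_sd["SED"], mean_sd["L_ACT_G"])
  expect_lt(mean_sd["L_ACT_G"], mean_sd["WALK"])
  expect_lt(mean_sd["WALK"], mean_sd["MV_ACT_G"])
  expect_lte(mean_sd["MV_ACT_G"], mean_sd["RUN"])
})

test_that("simulated recordings carry exact bout logs and zero-variance non-wear", {
  all_off <- simulate_recording(
    tibble::tibble(activity = "NONWEAR", duration_s = 24 * 3600),
    sample_rate = 5, seed = 1
  )
  vm <- vector_magnitude(all_off$recording)
  expect_equal(sd(vm), 0)

  plan <- tibble::tibble(
    activity = rep(c("WALK", "SED"), 8),
    duration_s = rep(3600, 16)
  )
  sim <- simulate_recording(plan, sample_rate = 5, seed = 2)
  expect_equal(nrow(sim$bout_log), 16)
  expect_equal(
    as.numeric(sim$bout_log$end - sim$bout_log$start, units = "secs"),
    rep(3600, 16)
  )
  expect_equal(sim$bout_log$start[-1], sim$bout_log$end[-16])

  expect_error(
    simulate_recording(tibble::tibble(activity = character(), duration_s = numeric())),
    class = "actikids_argument_error"
  )
})

test_that("a 29-minute non-wear block is logged but stays below the detector threshold", {
  plan <- tibble::tibble(
    activity = c("SED", "NONWEAR", "WALK"),
    duration_s = c(3600, 29 * 60, 3600)
  )
  sim <- simulate_recording(plan, sample_rate = 30, seed = 3)
  expect_true("NONWEAR" %in% sim$bout_log$activity)
  feats <- extract_features(sim$recording)
  nw <- detect_nonwear(feats)
  expect_equal(nrow(nw), 0)
})

test_that("noise-free cohort equals the deterministic mean curves exactly", {
  tc <- default_true_curves()
  co <- simulate_cohort(cohort_sim_params(
    n_children = 25, random_intercept_sd = 0, residual_sd = 0, seed = 5
  ))
  truth <- tc$curves$total_pa(co$days$age_years) +
    ifelse(co$days$sex == "male", 10, 0)
  expect_equal(co$days$total_pa, truth, tolerance = 1e-12)
  truth_sed <- tc$curves$sedentary(co$days$age_years) +
    ifelse(co$days$sex == "male", -8, 0)
  expect_equal(co$days$sedentary, truth_sed, tolerance = 1e-12)
})

test_that("cohort behaviour minutes and wear time are conserved exactly", {
  co <- simulate_cohort(cohort_sim_params(n_children = 50, seed = 6))
  d <- co$days
  expect_equal(d$sedentary + d$lpa + d$energetic_play, d$wear_minutes)
  expect_equal(d$walk + d$run + d$mv_act_g, d$energetic_play)
  expect_equal(d$lpa + d$energetic_play, d$total_pa)
  expect_true(all(table(d$child_id, d$wave) %in% c(0, 4:7)))
})

test_that("full attrition removes every wave-2 row", {
  co <- simulate_cohort(cohort_sim_params(
    n_children = 30, attrition_wave2 = 1, seed = 7
  ))
  expect_equal(sum(co$days$wave == 2), 0)
  expect_identical(
    simulate_cohort(cohort_sim_params(n_children = 30, seed = 8))$days,
    simulate_cohort(cohort_sim_params(n_children = 30, seed = 8))$days
  )
})

test_that("large-sample day means agree with the generating curve", {
  tc <- default_true_curves()
  co <- simulate_cohort(cohort_sim_params(n_children = 1000, seed = 9))
  d <- co$days
  resid <- d$total_pa - tc$curves$total_pa(d$age_years) -
    ifelse(d$sex == "male", 10, 0)
  child_means <- tapply(resid, d$child_id, mean)
  se <- sd(child_means) / sqrt(length(child_means))
  expect_lt(abs(mean(child_means)), 2 * se + 1e-9)
})
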