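# Trajectory mixed models, marginal means, Wald tests and design utilities.

tc <- default_true_curves()

test_that("the linear mixed model is exact in the noise-free limit", {
  co0 <- simulate_cohort(cohort_sim_params(
    n_children = 60, random_intercept_sd = 0, residual_sd = 0, seed = 2
  ))
  f0 <- suppressWarnings(fit_trajectory_lmm(co0$days, "total_pa", spec = tc$spec))
  m0 <- suppressWarnings(marginal_means(f0, ages = 2:7))
  truth <- tc$curves$total_pa(m0$age) + ifelse(m0$sex == "male", 10, 0)
  expect_equal(m0$estimate, truth, tolerance = 1e-6)
})

test_that("marginal total PA equals marginal LPA plus energetic play on exact data", {
  co0 <- simulate_cohort(cohort_sim_params(
    n_children = 60, random_intercept_sd = 0, residual_sd = 0, seed = 2
  ))
  fits <- lapply(c("total_pa", "lpa", "energetic_play"), function(o) {
    suppressWarnings(fit_trajectory_lmm(co0$days, o, spec = tc$spec))
  })
  mms <- lapply(fits, function(f) suppressWarnings(marginal_means(f, ages = 2:7)))
  expect_equal(
    mms[[1]]$estimate, mms[[2]]$estimate + mms[[3]]$estimate,
    tolerance = 1e-6
  )
})

test_that("variance components and the sex effect are recovered", {
  co <- simulate_cohort(cohort_sim_params(n_children = 500, seed = 1))
  fit <- fit_trajectory_lmm(co$days, "total_pa", spec = tc$spec)
  g <- glance(fit)
  expect_lt(abs(g$random_intercept_sd - 20) / 20, 0.15)
  expect_lt(abs(g$sigma - 30) / 30, 0.15)
  expect_true(g$converged)

  mm <- suppressWarnings(marginal_means(fit, ages = 2:7))
  gap <- mm$estimate[mm$sex == "male"] - mm$estimate[mm$sex == "female"]
  expect_lt(abs(mean(gap) - 10), 4)
})

test_that("marginal means respect covariate policy and recoding of labels", {
  co <- simulate_cohort(cohort_sim_params(n_children = 150, seed = 3))
  fit <- fit_trajectory_lmm(co$days, "total_pa",
    covariates = c("maternal_work", "season"), spec = tc$spec
  )
  mm_ref <- suppressWarnings(marginal_means(fit, ages = 3:6))
  # renaming factor labels (same structure, same reference position) leaves
  # the estimates unchanged
  d2 <- co$days
  levels(d2$maternal_work) <- c("W", "NW")
  fit2 <- fit_trajectory_lmm(d2, "total_pa",
    covariates = c("maternal_work", "season"), spec = tc$spec
  )
  mm2 <- suppressWarnings(marginal_means(fit2, ages = 3:6))
  expect_equal(mm_ref$estimate, mm2$estimate, tolerance = 1e-8)

  mm_pop <- suppressWarnings(marginal_means(fit, ages = 3:6, policy = "population"))
  expect_equal(nrow(mm_pop), nrow(mm_ref))
  expect_true(all(mm_ref$lo95 <= mm_ref$estimate & mm_ref$estimate <= mm_ref$hi95))
  expect_warning(marginal_means(fit, ages = c(1, 7)), "extrapolated")
})

test_that("confidence intervals tighten as the cohort grows", {
  w200 <- suppressWarnings(marginal_means(
    fit_trajectory_lmm(
      simulate_cohort(cohort_sim_params(n_children = 200, seed = 4))$days,
      "total_pa",
      spec = tc$spec
    ),
    ages = 2:7
  ))
  w800 <- suppressWarnings(marginal_means(
    fit_trajectory_lmm(
      simulate_cohort(cohort_sim_params(n_children = 800, seed = 4))$days,
      "total_pa",
      spec = tc$spec
    ),
    ages = 2:7
  ))
  expect_true(all((w800$hi95 - w800$lo95) < (w200$hi95 - w200$lo95)))
})

test_that("degenerate adherence is flagged, not estimated", {
  d <- tibble::tibble(
    child_id = sprintf("C%03d", 1:50), age_years = runif(50, 2, 7),
    sex = factor(rep(c("female", "male"), 25)), meets = 1L
  )
  g <- fit_trajectory_glmm(d, "meets")
  expect_true(g$degenerate)
  expect_false(g$converged)
  expect_error(marginal_means(g), class = "actikids_argument_error")
  expect_error(tidy(g), class = "actikids_argument_error")
})

test_that("the logistic model recovers a linear age effect on adherence", {
  adh <- simulate_adherence_cohort(n_children = 800, seed = 7)
  g <- fit_trajectory_glmm(adh$data, "meets")
  expect_true(g$converged)
  # average logit slope between ages 3 and 6 via a design contrast
  lv <- g$xlevels[[g$sex_col]]
  nd <- function(a) {
    tibble::tibble(age_years = a, sex = factor("female", levels = lv))
  }
  X <- actikids:::fixed_design(g, nd(6)) - actikids:::fixed_design(g, nd(3))
  b <- lme4::fixef(g$model)
  V <- as.matrix(vcov(g$model))
  slope <- as.numeric(X %*% b) / 3
  se <- sqrt(as.numeric(X %*% V %*% t(X))) / 3
  expect_lt(abs(slope - adh$truth$beta_age), 2 * se)
  # predicted adherence proportions stay inside (0, 1) on the grid
  mm <- suppressWarnings(marginal_means(g, ages = 2:7))
  expect_true(all(mm$estimate > 0 & mm$estimate < 1))
  expect_true(all(mm$lo95 > 0 & mm$hi95 < 1))
})

test_that("single-coefficient Wald tests equal the two-sided z-test", {
  co <- simulate_cohort(cohort_sim_params(n_children = 150, seed = 5))
  fit <- fit_trajectory_lmm(co$days, "total_pa", spec = tc$spec)
  td <- tidy(fit)
  w <- wald_joint_test(fit, terms = "sexmale")
  expect_equal(w$df, 1)
  expect_equal(w$p.value, td$p.value[td$term == "sexmale"], tolerance = 1e-10)
  expect_error(wald_joint_test(fit, terms = character()), class = "actikids_argument_error")
  expect_error(wald_joint_test(fit, terms = "nope"), class = "actikids_argument_error")
})

test_that("a strong simulated age-by-sex interaction is detected", {
  co <- simulate_cohort(cohort_sim_params(n_children = 300, seed = 6))
  d <- co$days
  d$total_pa <- d$total_pa + ifelse(d$sex == "male", 15 * (d$age_years - 4.5), 0)
  fit <- fit_trajectory_lmm(d, "total_pa", spec = tc$spec)
  expect_lt(wald_joint_test(fit)$p.value, 1e-3)
})

test_that("effect-size and power utilities reproduce the design arithmetic", {
  expect_equal(round(cohens_d(5, 42), 2), 0.12)
  expect_equal(cohens_d(0, 10), 0)
  expect_equal(cohens_d(42, 42), 1)
  expect_error(cohens_d(5, 0), class = "actikids_argument_error")
  # ~1,100 children per group give ~80% power for a 5-minute change, SD 42
  expect_gt(power_normal_approx(5, 42, 1100), 0.75)
  expect_lt(power_normal_approx(5, 42, 1100), 0.85)
  expect_gt(
    power_normal_approx(5, 42, 2000),
    power_normal_approx(5, 42, 500)
  )
})

test_that("composite sums follow the published-table convention", {
  boys <- sum_composites(lpa = 320.7, energetic_play = 34.7)
  expect_equal(boys$total_pa, 355.4, tolerance = 1e-9)
  girls <- sum_composites(lpa = 318.1, energetic_play = 30.3)
  expect_equal(girls$total_pa, 348.4, tolerance = 1e-9)
  parts <- sum_composites(lpa = 100, walk = 15, run = 5, mv_act_g = 20)
  expect_equal(parts$energetic_play, 40)
  expect_equal(parts$total_pa, 140)
  expect_equal(sum_composites(lpa = 0)$total_pa, 0)
  expect_error(sum_composites(lpa = -1), class = "actikids_argument_error")
})
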