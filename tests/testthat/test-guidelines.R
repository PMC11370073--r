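# Guideline rule assignment, per-child means and adherence scoring.

test_that("rules follow age and school enrolment", {
  expect_equal(assign_rule(2.4, FALSE), "EY_TODDLER")
  expect_equal(assign_rule(4.0, FALSE), "EY_PRESCHOOL")
  expect_equal(assign_rule(5.2, TRUE), "CYP_SCHOOL")
  # five-year-olds are scored by enrolment, not age
  expect_equal(assign_rule(5.2, FALSE), "EY_PRESCHOOL")
  expect_error(assign_rule(1.2, FALSE), class = "actikids_argument_error")
  expect_error(assign_rule(8.5, TRUE), class = "actikids_argument_error")
})

test_that("per-child means average valid days only, unweighted", {
  s <- tibble::tibble(
    subject_id = c("A", "A", "A"),
    total_pa = c(100, 300, 999),
    energetic_play = c(40, 60, 999),
    sedentary = c(400, 400, 999),
    lpa = c(60, 240, 999),
    walk = c(20, 30, 999), run = c(5, 10, 999), mv_act_g = c(15, 20, 999),
    wear_minutes = c(500, 700, 999),
    is_valid = c(TRUE, TRUE, FALSE),
    is_weekend = c(FALSE, TRUE, FALSE)
  )
  m <- mean_daily_behaviours(s)
  expect_equal(m$mean_tpa, 200)
  expect_equal(m$mean_mvpa, 50)
  expect_equal(m$n_valid_days, 2)
  one <- mean_daily_behaviours(s[1, ])
  expect_equal(one$mean_tpa, 100)
  expect_error(mean_daily_behaviours(s[3, ]), class = "actikids_argument_error")
})

test_that("adherence matches brute-force rule evaluation on the threshold grid", {
  grid <- expand.grid(
    tpa = c(179, 180, 181), mvpa = c(59, 60, 61),
    rule = c("EY_TODDLER", "EY_PRESCHOOL", "CYP_SCHOOL"),
    stringsAsFactors = FALSE
  )
  means <- tibble::tibble(
    subject_id = as.character(seq_len(nrow(grid))),
    mean_tpa = grid$tpa, mean_mvpa = grid$mvpa, rule_id = grid$rule
  )
  got <- meets_guideline(means)$meets
  want <- mapply(brute_rule, grid$rule, grid$tpa, grid$mvpa)
  expect_equal(got, unname(want))
  # inclusive boundaries in particular
  expect_true(brute_rule("EY_TODDLER", 180, 0))
  expect_false(brute_rule("EY_PRESCHOOL", 200, 59))
})

test_that("adherence is monotone and the preschool rule nests the toddler rule", {
  base <- tibble::tibble(subject_id = "A", mean_tpa = 185, mean_mvpa = 55)
  for (rule in guideline_rules()$rule_id) {
    m0 <- meets_guideline(dplyr::mutate(base, rule_id = rule))$meets
    up_tpa <- meets_guideline(dplyr::mutate(base, mean_tpa = 400, rule_id = rule))$meets
    up_mv <- meets_guideline(dplyr::mutate(base, mean_mvpa = 400, rule_id = rule))$meets
    expect_true(up_tpa >= m0)
    expect_true(up_mv >= m0)
  }
  set.seed(3)
  tpa <- runif(50, 100, 300)
  mv <- runif(50, 20, 90)
  pre <- rule_ok <- mapply(brute_rule, "EY_PRESCHOOL", tpa, mv)
  tod <- mapply(brute_rule, "EY_TODDLER", tpa, mv)
  expect_true(all(!pre | tod))
})

test_that("the every-day adherence variant is stricter than the mean variant", {
  s <- tibble::tibble(
    subject_id = rep("A", 4),
    total_pa = c(200, 200, 150, 250), # mean 200, one day below 180
    energetic_play = c(70, 70, 70, 70),
    sedentary = 300, lpa = 130, walk = 30, run = 10, mv_act_g = 30,
    wear_minutes = 500, is_valid = TRUE,
    is_weekend = c(FALSE, FALSE, FALSE, TRUE)
  )
  m <- mean_daily_behaviours(s)
  m$rule_id <- "EY_TODDLER"
  expect_true(meets_guideline(m)$meets)
  expect_false(meets_guideline(m, method = "every_day", summaries = s)$meets)
})

test_that("energetic-play deficit is the clamped shortfall", {
  expect_equal(energetic_play_deficit(60), 0)
  expect_equal(energetic_play_deficit(35.2), 24.8)
  expect_equal(energetic_play_deficit(80), 0)
  expect_equal(energetic_play_deficit(c(0, 59.5)), c(60, 0.5))
  expect_error(energetic_play_deficit(-1), class = "actikids_argument_error")
  # deficit + mvpa >= recommendation, equality iff below it
  mv <- c(0, 30, 60, 90)
  def <- energetic_play_deficit(mv)
  expect_true(all(def + mv >= 60))
  expect_equal(def + mv == 60, mv <= 60)
})
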