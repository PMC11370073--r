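# Non-wear detection, daily summaries and inclusion rules.

test_that("the 30-minute non-wear boundary is inclusive", {
  # 120 windows x 15 s = exactly 30 min -> one interval
  nw <- detect_nonwear(c(rep(0.001, 120), rep(0.5, 4)))
  expect_equal(nrow(nw), 1)
  expect_equal(nw$duration_min, 30)
  expect_equal(nw$start_window, 0)
  expect_equal(nw$end_window, 119)
  # 119 windows = 29.75 min -> none
  expect_equal(nrow(detect_nonwear(c(rep(0.001, 119), rep(0.5, 5)))), 0)
  # threshold is strict: vm_sd exactly at 13 mg counts as wear
  expect_equal(nrow(detect_nonwear(rep(0.013, 200))), 0)
  expect_equal(nrow(detect_nonwear(numeric(0))), 0)
})

test_that("detected intervals match the brute-force scanner on random sequences", {
  set.seed(101)
  for (i in 1:50) {
    sds <- ifelse(runif(2000) < 0.5, 0.001, 0.5)
    fast <- detect_nonwear(sds)
    slow <- brute_nonwear(sds)
    expect_equal(fast, slow)
    if (nrow(fast) > 1) {
      expect_true(all(diff(fast$start_window) > 0))
      expect_true(all(fast$start_window[-1] > fast$end_window[-nrow(fast)] + 1))
    }
    expect_true(all(fast$duration_min >= 30))
  }
})

mk_day_windows <- function(classes, start = "2019-05-06 08:00:00") {
  tibble::tibble(
    subject_id = "P1",
    window_start = as.POSIXct(start, tz = "UTC") + (seq_along(classes) - 1) * 15,
    class = classes
  )
}

test_that("an all-sedentary 480-minute day sits exactly on the validity boundary", {
  d <- summarize_day(mk_day_windows(rep("SED", 1920)))
  expect_equal(d$sedentary, 480)
  expect_equal(d$total_pa, 0)
  expect_equal(d$wear_minutes, 480)
  expect_true(d$is_valid)
  expect_false(d$is_weekend) # 2019-05-06 is a Monday
  # one window less -> invalid
  d2 <- summarize_day(mk_day_windows(rep("SED", 1919)))
  expect_false(d2$is_valid)
})

test_that("windows inside non-wear are excluded from behaviour and wear minutes", {
  win <- mk_day_windows(rep("SED", 2000))
  nw <- tibble::tibble(
    start = win$window_start[1],
    end = win$window_start[2000] + 15
  )
  d <- summarize_day(win, nonwear = nw)
  expect_equal(d$wear_minutes, 0)
  expect_equal(d$sedentary, 0)
  expect_equal(d$nonwear_minutes, 500)
  expect_false(d$is_valid)
  # partial overlap: behaviour + non-wear minutes partition the day
  nw2 <- tibble::tibble(start = win$window_start[101], end = win$window_start[300] + 15)
  d2 <- summarize_day(win, nonwear = nw2)
  expect_equal(d2$wear_minutes + d2$nonwear_minutes, 500)
})

test_that("days spanning midnight are rejected but summarize_days splits them", {
  win <- mk_day_windows(rep("WALK", 200), start = "2019-05-06 23:45:00")
  expect_error(summarize_day(win), class = "actikids_argument_error")
  days <- summarize_days(win)
  expect_equal(nrow(days), 2)
  expect_equal(sum(days$wear_minutes), 50)
})

test_that("ground-truth bout minutes are recovered when classes are known", {
  plan <- tibble::tibble(
    activity = c("SED", "WALK", "L_ACT_G", "RUN", "SED", "MV_ACT_G"),
    duration_s = c(3600, 1800, 2700, 900, 1800, 1200)
  )
  # window labels straight from the plan (each bout is a multiple of 15 s)
  classes <- rep(plan$activity, plan$duration_s / 15)
  d <- summarize_day(mk_day_windows(classes))
  expect_equal(d$sedentary, 90)
  expect_equal(d$walk, 30)
  expect_equal(d$lpa, 45)
  expect_equal(d$run, 15)
  expect_equal(d$mv_act_g, 20)
  expect_equal(d$energetic_play, 65)
  expect_equal(d$total_pa, 110)
  expect_equal(d$wear_minutes, sum(plan$duration_s) / 60)
})

test_that("the inclusion rule matches exhaustive enumeration and is monotone", {
  mk_summaries <- function(n_valid_wk, n_valid_we) {
    n <- n_valid_wk + n_valid_we
    if (n == 0) {
      return(tibble::tibble(
        subject_id = "A", is_valid = FALSE, is_weekend = FALSE
      ))
    }
    tibble::tibble(
      subject_id = "A",
      is_valid = TRUE,
      is_weekend = rep(c(FALSE, TRUE), c(n_valid_wk, n_valid_we))
    )
  }
  for (wk in 0:7) {
    for (we in 0:2) {
      got <- select_valid_subjects(mk_summaries(wk, we))$include
      want <- (wk + we >= 4) && (we >= 1)
      expect_identical(got, want)
      # monotone: one more valid weekday never flips include -> exclude
      more <- select_valid_subjects(mk_summaries(wk + 1, we))$include
      expect_true(more >= got)
    }
  }
  # 3 valid weekdays + 1 valid Saturday = 4 valid days incl. weekend -> include
  expect_true(select_valid_subjects(mk_summaries(3, 1))$include)
  # 4 valid weekdays, no weekend -> exclude
  expect_false(select_valid_subjects(mk_summaries(4, 0))$include)
})
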