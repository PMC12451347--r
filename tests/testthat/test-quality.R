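test_that("rosendaal resolves analytic crossing times exactly", {
  # constant in-range INR: all time in range
  expect_equal(rosendaal(c(0, 30), c(2.5, 2.5), 2, 3, 0, 30),
               c(ttr = 100, tbr = 0, tar = 0))
  # 2.0 -> 4.0 over 10 days crosses the upper limit at day 5
  expect_equal(rosendaal(c(0, 10), c(2, 4), 2, 3, 0, 10),
               c(ttr = 50, tbr = 0, tar = 50))
  # 1.0 -> 3.0 over 10 days crosses the lower limit at day 5
  expect_equal(rosendaal(c(0, 10), c(1, 3), 2, 3, 0, 10),
               c(ttr = 50, tbr = 50, tar = 0))
  # boundary value counts as in range
  expect_equal(rosendaal(c(0, 10), c(3, 3), 2, 3, 0, 10)[["ttr"]], 100)
})

test_that("rosendaal conserves time and matches grid integration", {
  withr::with_seed(2024, {
    for (rep in 1:150) {
      tr <- random_trajectory()
      got <- rosendaal(tr$t, tr$y, tr$low, tr$high, tr$ws, tr$we)
      if (all(is.na(got))) next
      expect_equal(sum(got), 100, tolerance = 1e-6)
      want <- grid_time_in_range(tr$t, tr$y, tr$low, tr$high, tr$ws, tr$we)
      expect_equal(got, want, tolerance = 0.05)
    }
  })
})

test_that("rosendaal clips to exit and covers only observed time", {
  # exit halfway through: only days 0-15 are evaluated
  full <- rosendaal(c(0, 30), c(2, 4), 2, 3, 0, 30)
  clipped <- rosendaal(c(0, 30), c(2, 4), 2, 3, 0, 30, exit = 15)
  expect_equal(full, c(ttr = 50, tbr = 0, tar = 50))
  expect_equal(clipped, c(ttr = 100, tbr = 0, tar = 0))
  # no trajectory inside the window -> missing, not zero
  expect_true(all(is.na(rosendaal(c(40, 50), c(2.5, 2.5), 2, 3, 0, 30))))
  # full-window denominator counts uncovered time in the denominator
  cfg <- quality_config(denominator = "full_window")
  part <- rosendaal(c(0, 15), c(2.5, 2.5), 2, 3, 0, 30, config = cfg)
  expect_equal(part[["ttr"]], 50)
})

test_that("metrics are invariant to shifting all dates and windows", {
  withr::with_seed(7, {
    for (rep in 1:25) {
      tr <- random_trajectory()
      k <- sample(-2000:2000, 1)
      a <- rosendaal(tr$t, tr$y, tr$low, tr$high, tr$ws, tr$we)
      b <- rosendaal(tr$t + k, tr$y, tr$low, tr$high, tr$ws + k, tr$we + k)
      expect_equal(a, b)
      expect_equal(vgr(tr$t, tr$y, tr$ws, tr$we),
                   vgr(tr$t + k, tr$y, tr$ws + k, tr$we + k))
    }
  })
})

test_that("raising the upper target limit never lowers TTR or raises TAR", {
  withr::with_seed(11, {
    for (rep in 1:25) {
      tr <- random_trajectory()
      a <- rosendaal(tr$t, tr$y, 2, 3, tr$ws, tr$we)
      b <- rosendaal(tr$t, tr$y, 2, 3.5, tr$ws, tr$we)
      if (any(is.na(a))) next
      expect_gte(b[["ttr"]], a[["ttr"]] - 1e-9)
      expect_lte(b[["tar"]], a[["tar"]] + 1e-9)
    }
  })
})

test_that("vgr evaluates the mean squared change per week", {
  expect_equal(vgr(c(0, 7), c(2, 3), 0, 30), 1.0)
  expect_equal(vgr(c(0, 7, 21), c(2, 3, 3), 0, 30), 0.5)
  expect_equal(vgr(c(0, 10, 20), c(2.5, 2.5, 2.5), 0, 30), 0)
  # pairs whose later member is outside the window are excluded
  expect_equal(vgr(c(0, 7, 40), c(2, 3, 9), 0, 30), 1.0)
  # day-denominator config scales by 7
  expect_equal(vgr(c(0, 7), c(2, 3), 0, 30,
                   config = quality_config(vgr_denominator = "days")), 1 / 7)
})

test_that("vgr scales inversely with time dilation", {
  withr::with_seed(5, {
    t <- cumsum(runif(6, 3, 12)); y <- runif(6, 1.5, 4.5)
    v1 <- vgr(t, y, 0, max(t) + 1)
    v3 <- vgr(t * 3, y, 0, 3 * (max(t) + 1))
    expect_equal(v3, v1 / 3, tolerance = 1e-12)
  })
})

test_that("INR proportions count measurements with inclusive boundaries", {
  p <- inr_proportions(c(2.5, 3.5, 5.0), 2, 3)
  expect_equal(unname(p), c(100 / 3, 0, 200 / 3, 100 / 3, 0))
  expect_equal(sum(p[c("prop_in", "prop_below", "prop_above")]), 100)
  expect_equal(inr_proportions(3.0, 2, 3)[["prop_in"]], 100)
  expect_equal(inr_proportions(c(5, 8), 2, 3)[["prop_ge8"]], 50)
  expect_true(all(is.na(inr_proportions(numeric(), 2, 3))))
})

test_that("dose changes classify with an inclusive 10% threshold", {
  expect_identical(classify_dose_change(2.00, 1.80), "reduction")
  expect_identical(classify_dose_change(2.00, 2.19), "none")
  expect_identical(classify_dose_change(2.00, 2.20), "increase")
  expect_identical(classify_dose_change(0, 0.5), "increase")
  expect_identical(classify_dose_change(0, 0), "none")
  expect_identical(classify_dose_change(2, NA), NA_character_)
  expect_identical(classify_dose_change(2, c(1.7, 2.3)),
                   c("reduction", "increase"))
})

test_that("monitoring statistics count in-window measurements and gaps", {
  m <- monitoring_stats(c(2, 18), 0, 30)
  expect_identical(m$n_inr, 2L)
  expect_equal(m$median_interval_days, 16)
  m0 <- monitoring_stats(numeric(), 0, 30)
  expect_identical(m0$n_inr, 0L)
  expect_true(is.na(m0$median_interval_days))
  # gap straddling the window start counts through its later member
  m2 <- monitoring_stats(c(-4, 6, 20), 0, 30)
  expect_identical(m2$n_inr, 2L)
  expect_equal(m2$median_interval_days, 12)
})

test_that("window eligibility follows the two-measurement rule with borrowing", {
  cal <- default_ramadan_calendar()
  wt <- build_window_table(cal)
  d0 <- cal$ramadan_start[cal$year == 2016] - 60

  run_q <- function(dates, values = NULL) {
    tabs <- tiny_tables(inr_dates = dates, inr = values)
    fu <- compute_follow_up(tabs$subjects, tabs$episodes, tabs$dispensings,
                            tabs$events, wt)
    window_quality(tabs, fu, wt)
  }
  # two INRs inside window 0 -> eligible there
  q <- run_q(d0 + c(65, 80))
  expect_true(q$eligible[q$window == 0])
  # one INR inside window 0 plus one in window -1 -> eligible (borrowed)
  q <- run_q(d0 + c(50, 70))
  expect_true(q$eligible[q$window == 0])
  # single isolated INR, nothing in the 30 days before -> ineligible
  q <- run_q(d0 + 70)
  expect_false(q$eligible[q$window == 0])
  expect_true(is.na(q$ttr[q$window == 0]))     # missing, never zero
  expect_identical(q$n_inr[q$window == 0], 1L)
})

test_that("switch flags fire only in the window containing the first switch", {
  cal <- default_ramadan_calendar()
  wt <- build_window_table(cal)
  d0 <- cal$ramadan_start[cal$year == 2016] - 60
  tabs <- tiny_tables(doac_date = d0 + 70)
  tabs$episodes <- tibble::tibble(
    subject_id = "A",
    start = c(d0 - 400, d0 + 100),
    end = c(d0 + 99, as.Date(NA)),
    vka_type = c("acenocoumarol", "phenprocoumon")
  )
  fu <- compute_follow_up(tabs$subjects, tabs$episodes, tabs$dispensings,
                          tabs$events, wt)
  q <- window_quality(tabs, fu, wt)
  expect_identical(q$window[q$switched_doac], 0L)
  # follow-up already ended at the DOAC switch, before the VKA type change
  expect_identical(fu$exit, d0 + 70)
  expect_false(any(q$switched_vka_type))
})
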