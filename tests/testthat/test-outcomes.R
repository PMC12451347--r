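test_that("with no censoring or competing events the CIF equals x/n", {
  time <- rep(30, 3800)
  status <- rep("censor", 3800)
  status[1:20] <- "event"
  time[1:20] <- seq(1, 29, length.out = 20)
  res <- cuminc_30d(time, status)
  expect_equal(res$estimate, 20 / 3800, tolerance = 1e-12)
  expect_identical(res$n_events, 20L)
  expect_true(res$ci_low < res$estimate && res$estimate < res$ci_high)
  expect_equal(cuminc_30d(rep(30, 50), rep("censor", 50))$estimate, 0)
})

test_that("CIF matches a hand product-sum with censoring and competing death", {
  time <- c(2, 4, 5, 7, 10, 12, 20, 30)
  status <- c("event", "censor", "competing", "event", "censor", "event",
              "censor", "censor")
  res <- cuminc_30d(time, status)
  expect_equal(res$estimate, 67 / 144, tolerance = 1e-12)
  expect_equal(res$estimate, hand_aj_cif(time, status), tolerance = 1e-12)
  # randomized configurations against the same oracle
  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- sample(4:12, 1)
      tm <- sample(1:40, n, replace = FALSE)
      st <- sample(c("event", "competing", "censor"), n, replace = TRUE)
      expect_equal(cuminc_30d(tm, st)$estimate, hand_aj_cif(tm, st),
                   tolerance = 1e-10)
    }
  })
})

test_that("Aalen-Johansen state probabilities close to one", {
  withr::with_seed(17, {
    tm <- sample(1:40, 12, replace = FALSE)
    st <- sample(c("event", "competing", "censor"), 12, replace = TRUE,
                 prob = c(.4, .4, .2))
    cif_e <- cuminc_30d(tm, st)$estimate
    cif_c <- cuminc_30d(tm, ifelse(st == "event", "competing",
                                   ifelse(st == "competing", "event", st))
    )$estimate
    surv <- 1 - hand_aj_cif(tm, st) -
      hand_aj_cif(tm, ifelse(st == "event", "competing",
                             ifelse(st == "competing", "event", st)))
    expect_equal(cif_e + cif_c + surv, 1, tolerance = 1e-10)
  })
})

test_that("KM mortality equals the hand product-limit value", {
  time <- c(3, 5, 8, 12, 20, 30, 30, 30, 30, 30)
  death <- c(0, 1, 0, 1, 1, 0, 0, 0, 0, 0)
  res <- km_mortality(time, death)
  expect_equal(res$estimate, 23 / 63, tolerance = 1e-12)
  expect_equal(res$estimate, hand_km_mortality(time, death), tolerance = 1e-12)
  expect_equal(km_mortality(rep(30, 10), rep(0, 10))$estimate, 0)
  all_die <- km_mortality(rep(1, 5), rep(1, 5))
  expect_equal(all_die$estimate, 1)
})

test_that("exact Poisson intervals reproduce the chi-squared quantiles", {
  res <- incidence_rate(10, 100)
  expect_equal(res$ir, 10)
  expect_equal(res$ci_low, qchisq(0.025, 20) / 2, tolerance = 1e-12)
  expect_equal(res$ci_high, qchisq(0.975, 22) / 2, tolerance = 1e-12)
  z <- incidence_rate(0, 50)
  expect_identical(z$ir, 0)
  expect_identical(z$ci_low, 0)
  expect_gt(z$ci_high, 0)
  expect_error(incidence_rate(3, 0), "positive")
  # doubling x and T roughly halves relative CI width
  a <- incidence_rate(10, 100); b <- incidence_rate(20, 200)
  expect_lt((b$ci_high - b$ci_low) / b$ir, (a$ci_high - a$ci_low) / a$ir)
})

test_that("exact Poisson intervals are conservative at their true coverage", {
  # exact (Garwood) intervals guarantee >= 95% coverage; at lambda*T = 5
  # the true coverage, computable by direct enumeration, is ~0.9796
  lambda_t <- 5
  xs <- 0:60
  lo_all <- ifelse(xs == 0, 0, qchisq(0.025, 2 * xs) / 2)
  hi_all <- qchisq(0.975, 2 * xs + 2) / 2
  exact_cover <- sum(dpois(xs, lambda_t) * (lo_all <= lambda_t &
                                              lambda_t <= hi_all))
  expect_gte(exact_cover, 0.95)
  withr::with_seed(12345, x <- rpois(10000, lambda_t))
  lo <- ifelse(x == 0, 0, qchisq(0.025, 2 * x) / 2)
  hi <- qchisq(0.975, 2 * x + 2) / 2
  cover <- mean(lo <= lambda_t & lambda_t <= hi)
  expect_gte(cover, 0.95)
  expect_lt(abs(cover - exact_cover), 3 * sqrt(exact_cover *
                                                 (1 - exact_cover) / 10000))
})

test_that("window_incidence assembles counts, rates and CIFs per window", {
  cal <- default_ramadan_calendar()
  wt <- build_window_table(cal)
  d0 <- cal$ramadan_start[cal$year == 2016] - 60
  n <- 40
  ids <- sprintf("p%03d", 1:n)
  subjects <- tibble::tibble(subject_id = ids, cohort_label = "t",
                             year = 2016L, age_at_d0 = 60, sex = "f",
                             target_low = 2, target_high = 3)
  episodes <- tibble::tibble(subject_id = ids, start = d0 - 300,
                             end = as.Date(NA), vka_type = "acenocoumarol")
  dispensings <- tibble::tibble(subject_id = ids, date = d0 - 30,
                                drug = "vka")
  # two bleeds in window 0, one death in window 1
  events <- tibble::tibble(
    subject_id = c("p001", "p002", "p003"),
    date = c(d0 + 65, d0 + 75, d0 + 100),
    event_class = c("major_bleeding", "major_bleeding", "death")
  )
  fu <- compute_follow_up(subjects, episodes, dispensings, events, wt)
  inc <- window_incidence(events, fu, wt)
  w0 <- inc[inc$window == 0 & inc$outcome == "major_bleeding", ]
  expect_identical(w0$n_at_risk, 40L)
  expect_identical(w0$n_events, 2L)
  expect_equal(w0$cuminc_per_1000, 1000 * 2 / 40, tolerance = 1e-9)
  w1 <- inc[inc$window == 1 & inc$outcome == "all_cause_mortality", ]
  expect_identical(w1$n_at_risk, 38L)
  expect_identical(w1$n_events, 1L)
  # composite counts the bleeds but not the death
  comp <- inc[inc$outcome == "composite", ]
  expect_identical(sum(comp$n_events), 2L)
  expect_true(all(comp$n_events <= comp$n_at_risk))
  expect_true(all(is.na(comp$ir) | comp$ir == 100 * comp$n_events /
                    comp$person_years))
})
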