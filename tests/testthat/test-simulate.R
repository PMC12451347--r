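test_that("a fixed seed reproduces the cohort exactly; n = 0 is valid", {
  cfg <- sim_config(n_subjects = 25, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  expect_identical(nrow(validate_cohort_tables(a)), 0L)
  empty <- simulate_cohort(sim_config(n_subjects = 0))
  expect_true(all(vapply(empty, nrow, 1L) == 0))
  expect_identical(nrow(validate_cohort_tables(empty)), 0L)
})

test_that("growing the cohort leaves earlier subjects untouched", {
  small <- simulate_cohort(sim_config(n_subjects = 10, seed = 6))
  large <- simulate_cohort(sim_config(n_subjects = 20, seed = 6))
  expect_identical(small$inr,
                   dplyr::semi_join(large$inr, small$subjects,
                                    by = "subject_id"))
})

test_that("noise-free trajectories are pinned to the range midpoint", {
  cfg <- sim_config(n_subjects = 8, seed = 2, sigma_between = 0,
                    sigma_process = 0, sigma_measure = 0,
                    ramadan_inr_shift = 0, target_mix = c(1, 0, 0),
                    event_risk_30d = c(major_bleeding = 0),
                    death_risk_30d = 0, doac_switch_prob = 0,
                    discontinuation_prob = 0)
  tabs <- simulate_cohort(cfg)
  expect_true(all(tabs$inr$inr == 2.5))
  wt <- build_window_table(cfg$calendar)
  fu <- compute_follow_up(tabs$subjects, tabs$episodes, tabs$dispensings,
                          tabs$events, wt)
  q <- window_quality(tabs, fu, wt)
  expect_true(all(q$ttr[q$eligible] == 100))
})

test_that("a large noise-free Ramadan shift saturates window 0 above range", {
  cfg <- sim_config(n_subjects = 8, seed = 2, sigma_between = 0,
                    sigma_process = 0, sigma_measure = 0,
                    ramadan_inr_shift = 1.0, target_mix = c(1, 0, 0),
                    event_risk_30d = c(major_bleeding = 0),
                    death_risk_30d = 0, doac_switch_prob = 0,
                    discontinuation_prob = 0)
  tabs <- simulate_cohort(cfg)
  wt <- build_window_table(cfg$calendar)
  fu <- compute_follow_up(tabs$subjects, tabs$episodes, tabs$dispensings,
                          tabs$events, wt)
  q <- window_quality(tabs, fu, wt)
  in_w0 <- q$eligible & q$window == 0 & !is.na(q$prop_above)
  expect_true(all(q$prop_above[in_w0] == 100))
  expect_true(all(q$prop_above[q$eligible & q$window == -2 &
                                 !is.na(q$prop_above)] == 0))
})

test_that("visit intervals match the configured 16-day median schedule", {
  tabs <- simulate_cohort(sim_config(n_subjects = 300, seed = 13))
  gaps <- tabs$inr |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(g = list(diff(as.numeric(date)))) |>
    dplyr::pull(g) |>
    unlist()
  expect_gt(median(gaps), 16 - 1.5)
  expect_lt(median(gaps), 16 + 1.5)
})

test_that("event risks agree with the exponential closed form", {
  risk30 <- 0.04
  cfg <- sim_config(n_subjects = 4000, seed = 77,
                    event_risk_30d = c(major_bleeding = risk30),
                    death_risk_30d = 0, doac_switch_prob = 0,
                    discontinuation_prob = 0)
  tabs <- simulate_cohort(cfg)
  wt <- build_window_table(cfg$calendar)
  fu <- compute_follow_up(tabs$subjects, tabs$episodes, tabs$dispensings,
                          tabs$events, wt)
  inc <- window_incidence(tabs$events, fu, wt)
  w0 <- inc[inc$window == -2 & inc$outcome == "major_bleeding", ]
  p_expect <- 1 - exp(-risk30 / 30 * 30)
  mc_se <- sqrt(p_expect * (1 - p_expect) / w0$n_at_risk)
  expect_lt(abs(w0$cuminc_per_1000 / 1000 - p_expect), 3 * mc_se)
})

test_that("competing death suppresses cause-specific cumulative incidence", {
  lam_e <- 0.05 / 30; lam_d <- 0.30 / 30
  cfg <- sim_config(n_subjects = 3000, seed = 88,
                    event_risk_30d = c(venous_te = 0.05),
                    death_risk_30d = 0.30, doac_switch_prob = 0,
                    discontinuation_prob = 0)
  tabs <- simulate_cohort(cfg)
  wt <- build_window_table(cfg$calendar)
  fu <- compute_follow_up(tabs$subjects, tabs$episodes, tabs$dispensings,
                          tabs$events, wt)
  inc <- window_incidence(tabs$events, fu, wt,
                          outcomes = list(venous_te = "venous_te"))
  w0 <- inc[inc$window == -2 & inc$outcome == "venous_te", ]
  # analytic competing-exponentials cumulative incidence at day 30
  p_expect <- lam_e / (lam_e + lam_d) * (1 - exp(-(lam_e + lam_d) * 30))
  p_naive <- 1 - exp(-lam_e * 30)
  expect_lt(p_expect, p_naive)
  mc_se <- sqrt(p_expect * (1 - p_expect) / w0$n_at_risk)
  expect_lt(abs(w0$cuminc_per_1000 / 1000 - p_expect), 3 * mc_se)
})

test_that("the closed-form marginal SD describes simulated INR dispersion", {
  cfg <- sim_config(n_subjects = 500, seed = 10, target_mix = c(1, 0, 0))
  tabs <- simulate_cohort(cfg)
  expect_lt(abs(sd(tabs$inr$inr) - sim_marginal_sd(cfg)), 0.03)
})
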