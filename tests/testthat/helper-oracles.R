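# Independent oracles used to cross-check the package's estimators.
# These deliberately share no code with the implementation.

# Time-in-range by brute-force numerical integration of the linearly
# interpolated INR trajectory on a fine grid (default 1-minute steps).
grid_time_in_range <- function(t, y, low, high, ws, we, exit = we,
                               step = 1 / 1440) {
  t <- as.numeric(t); ws <- as.numeric(ws); we <- as.numeric(we)
  ub <- min(we, as.numeric(exit), max(t))
  lb <- max(ws, min(t))
  if (ub - lb <= 0) return(c(ttr = NA_real_, tbr = NA_real_, tar = NA_real_))
  grid <- seq(lb, ub, by = step)
  yy <- approx(t, y, xout = grid, rule = 1)$y
  below <- mean(yy < low)
  above <- mean(yy > high)
  inside <- 1 - below - above
  c(ttr = 100 * inside, tbr = 100 * below, tar = 100 * above)
}

# Step-by-step Aalen-Johansen product-sum for the target cause: at each
# event time, CIF += S(t-) * d_target / n_at_risk, with S the all-cause
# product-limit survival.
hand_aj_cif <- function(time, status, t_eval = 30) {
  ord <- order(time)
  time <- time[ord]; status <- as.character(status)[ord]
  s_minus <- 1; cif <- 0; n <- length(time)
  for (tt in sort(unique(time[status != "censor" & time <= t_eval]))) {
    at_risk <- sum(time >= tt)
    d_event <- sum(time == tt & status == "event")
    d_comp <- sum(time == tt & status == "competing")
    cif <- cif + s_minus * d_event / at_risk
    s_minus <- s_minus * (1 - (d_event + d_comp) / at_risk)
  }
  cif
}

# Hand product-limit estimator of mortality by t_eval.
hand_km_mortality <- function(time, death, t_eval = 30) {
  s <- 1
  for (tt in sort(unique(time[death == 1 & time <= t_eval]))) {
    at_risk <- sum(time >= tt)
    d <- sum(time == tt & death == 1)
    s <- s * (1 - d / at_risk)
  }
  1 - s
}

# Random piecewise-linear INR trajectory inside a 30-day window, with an
# anchor before the window start.
random_trajectory <- function() {
  n <- sample(3:8, 1)
  t <- sort(c(runif(1, -20, -1), runif(n - 1, 0, 40)))
  y <- round(runif(n, 0.9, 6.5), 2)
  list(t = t, y = y, low = 2, high = 3, ws = 0, we = 30)
}

# Minimal valid five-table cohort around one subject, eligible by design.
tiny_tables <- function(subject_id = "A", year = 2016L,
                        inr_dates = NULL, inr = NULL, dose = NULL,
                        target = c(2, 3), events = NULL,
                        doac_date = NULL, episode_end = NA) {
  cal <- default_ramadan_calendar()
  d0 <- cal$ramadan_start[cal$year == year] - 60
  if (is.null(inr_dates)) inr_dates <- d0 + c(-10, 5, 20, 40, 70, 100, 130)
  if (is.null(inr)) inr <- rep(2.5, length(inr_dates))
  if (is.null(dose)) dose <- rep(2, length(inr_dates))
  disp <- tibble::tibble(subject_id = subject_id, date = d0 - 30,
                         drug = "vka")
  if (!is.null(doac_date)) {
    disp <- dplyr::bind_rows(disp, tibble::tibble(
      subject_id = subject_id, date = as.Date(doac_date), drug = "doac"))
  }
  list(
    subjects = tibble::tibble(
      subject_id = subject_id, cohort_label = "test", year = year,
      age_at_d0 = 60, sex = "female",
      target_low = target[1], target_high = target[2]
    ),
    episodes = tibble::tibble(
      subject_id = subject_id, start = d0 - 400,
      end = as.Date(episode_end), vka_type = "acenocoumarol"
    ),
    dispensings = disp,
    inr = tibble::tibble(
      subject_id = subject_id, date = as.Date(inr_dates, origin = "1970-01-01"),
      inr = inr, target_low = target[1], target_high = target[2],
      dose = dose
    ),
    events = events %||% tibble::tibble(
      subject_id = character(), date = as.Date(character()),
      event_class = character()
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
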