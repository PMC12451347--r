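#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. Defaults emulate the
#' structure of the anticoagulation-clinic registry data the pipeline is
#' designed for: ~16-day median INR visit intervals (IQR ~10-24), target
#' ranges 2.0-3.0 / 2.5-3.5 / 3.0-4.0, feedback dosing, rare clinical
#' events (composite 30-day risk ~5 per 1000), competing death,
#' DOAC-switch censoring and an optional additive INR shift during the
#' Ramadan window.
#'
#' The observed INR at a visit is `midpoint + b_i + x(t) + delta *
#' 1[date in Ramadan window] + measurement noise`, floored at 0.8, where
#' `b_i ~ N(0, sigma_between^2)` is a subject offset and `x(t)` a
#' mean-reverting Ornstein-Uhlenbeck process with stationary SD
#' `sigma_process` and correlation time `ou_tau` days. The marginal SD of
#' an observed INR is therefore
#' `sqrt(sigma_between^2 + sigma_process^2 + sigma_measure^2)`
#' (see [sim_marginal_sd()]), which makes tail probabilities above the
#' target range available in closed form.
#'
#' @param n_subjects Number of subjects (default 3835).
#' @param cohort_label Label stored on every subject.
#' @param calendar Ramadan calendar tibble.
#' @param year_probs Named numeric: sampling weights of anchor years.
#' @param target_mix Probabilities of target ranges 2.0-3.0, 2.5-3.5,
#'   3.0-4.0 (must sum to 1).
#' @param visit_meanlog,visit_sdlog Log-normal visit-gap parameters
#'   (days); defaults give median 16, IQR ~10.5-24.5.
#' @param ou_tau OU correlation time (days).
#' @param sigma_between,sigma_process,sigma_measure INR SD components.
#' @param ramadan_inr_shift Additive INR shift delta during window 0.
#' @param dose_adjust_prob Probability an out-of-range INR triggers a dose
#'   adjustment at that visit.
#' @param dose_step_large_prob Probability an adjustment is clinically
#'   relevant (>= 10%).
#' @param event_risk_30d Named per-class 30-day event risks.
#' @param death_risk_30d 30-day risk of death.
#' @param doac_switch_prob Probability of a DOAC switch during the 150-day
#'   follow-up (uniform switch date).
#' @param discontinuation_prob Probability the VKA episode ends during
#'   follow-up.
#' @param aceno_prob Probability of acenocoumarol (vs phenprocoumon).
#' @param seed Integer seed. Each subject draws from its own substream
#'   derived from `seed` and the subject index, so changing `n_subjects`
#'   does not reshuffle existing subjects.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 3835,
                       cohort_label = "ramadan",
                       calendar = default_ramadan_calendar(),
                       year_probs = c(`2013` = 0.106, `2014` = 0.131,
                                      `2015` = 0.148, `2016` = 0.151,
                                      `2017` = 0.144, `2018` = 0.141,
                                      `2019` = 0.179),
                       target_mix = c(0.43, 0.47, 0.10),
                       visit_meanlog = log(16), visit_sdlog = 0.62,
                       ou_tau = 20,
                       sigma_between = 0.30, sigma_process = 0.45,
                       sigma_measure = 0.20,
                       ramadan_inr_shift = 0,
                       dose_adjust_prob = 0.25,
                       dose_step_large_prob = 0.5,
                       event_risk_30d = c(major_bleeding = 0.0026,
                                          ischemic_stroke = 0.0012,
                                          tia = 0.0006,
                                          myocardial_infarction = 0.0006,
                                          other_arterial_te = 0.0006,
                                          venous_te = 0.0005),
                       death_risk_30d = 0.0005,
                       doac_switch_prob = 0.015,
                       discontinuation_prob = 0.01,
                       aceno_prob = 0.82,
                       seed = 1L) {
  stopifnot(abs(sum(target_mix) - 1) < 1e-8,
            all(target_mix >= 0), all(event_risk_30d >= 0),
            death_risk_30d >= 0, n_subjects >= 0)
  cfg <- as.list(environment())
  cfg$year_probs <- year_probs / sum(year_probs)
  structure(cfg, class = "sim_config")
}

#' Bundled simulation presets
#'
#' `"null"`: no Ramadan shift (delta = 0), stationary hazards -- the
#' negative-control configuration under which every window-level metric
#' has the same expectation. `"ramadan-shift"`: delta = 0.3 INR units
#' during the Ramadan window, the end-to-end recovery scenario.
#'
#' @param preset `"null"` or `"ramadan-shift"`.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_preset <- function(preset = c("null", "ramadan-shift"), ...) {
  preset <- match.arg(preset)
  delta <- if (preset == "ramadan-shift") 0.3 else 0
  sim_config(ramadan_inr_shift = delta, ...)
}

#' Marginal SD of a simulated observed INR
#'
#' @param config A [sim_config()].
#' @return `sqrt(sigma_between^2 + sigma_process^2 + sigma_measure^2)`.
#' @export
sim_marginal_sd <- function(config) {
  sqrt(config$sigma_between^2 + config$sigma_process^2 +
         config$sigma_measure^2)
}

#' Closed-form expected shift in the proportion of INRs above range
#'
#' Under the generator's marginal normal model, the expected difference in
#' `prop_above` (percent) between the Ramadan window and a pre-Ramadan
#' window is `100 * (P(Z > (h - delta)/s) - P(Z > h/s))`, where `h` is the
#' half-width of the target range (0.5 INR units for all three standard
#' ranges) and `s` the marginal SD.
#'
#' @param config A [sim_config()].
#' @param half_width Distance from range midpoint to the upper limit.
#' @return Expected shift in percentage points.
#' @export
expected_prop_above_shift <- function(config, half_width = 0.5) {
  s <- sim_marginal_sd(config)
  100 * (stats::pnorm((half_width - config$ramadan_inr_shift) / s,
                      lower.tail = FALSE) -
           stats::pnorm(half_width / s, lower.tail = FALSE))
}

target_ranges <- cbind(low = c(2.0, 2.5, 3.0), high = c(3.0, 3.5, 4.0))

subject_seed <- function(seed, i) {
  (as.numeric(seed) * 1000003 + i * 7919) %% 2147483647
}

#' Generate a synthetic cohort
#'
#' Produces the five canonical cohort tables for `n_subjects` synthetic
#' VKA users. Each subject has a VKA episode starting well before
#' follow-up (so the cohort filters pass at the configured rates), 90-day
#' VKA dispensing cycles, a visit schedule from 90 days before follow-up
#' entry to its end, an OU latent INR with feedback dosing, optional DOAC
#' switch and discontinuation, and exponential event/death times. Output
#' is byte-deterministic for a fixed config.
#'
#' @param config A [sim_config()].
#' @return Named list of tibbles: `subjects`, `episodes`, `dispensings`,
#'   `inr`, `events` (passing [validate_cohort_tables()]).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  cal <- config$calendar
  years <- as.integer(names(config$year_probs))
  stopifnot(all(years %in% cal$year))

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- with_private_seed(subject_seed(config$seed, i),
                                   simulate_subject(i, config, years))
  }
  tables <- list(
    subjects = assemble_rows(rows, "subject", "subjects"),
    episodes = assemble_rows(rows, "episodes", "episodes"),
    dispensings = assemble_rows(rows, "dispensings", "dispensings"),
    inr = assemble_rows(rows, "inr", "inr"),
    events = assemble_rows(rows, "events", "events")
  )
  sort_cohort_tables(tables)
}

simulate_subject <- function(i, config, years) {
  sid <- sprintf("S%05d", i)
  year <- years[sample.int(length(years), 1, prob = config$year_probs)]
  cal_row <- config$calendar[config$calendar$year == year, ]
  wins <- build_windows(cal_row$ramadan_start, cal_row$ramadan_end)
  d0 <- wins$start[1]
  d5 <- wins$end[5]
  ram_start <- wins$start[3]
  ram_end <- wins$end[3]

  age <- min(max(rnorm(1, 65, 13), 18.5), 95)
  tr <- target_ranges[sample.int(3, 1, prob = config$target_mix), ]
  vka_type <- if (runif(1) < config$aceno_prob) "acenocoumarol" else
    "phenprocoumon"

  epi_start <- d0 - round(runif(1, 150, 600))
  disc <- runif(1) < config$discontinuation_prob
  epi_end <- if (disc) d0 + round(runif(1, 10, 149)) else as.Date(NA)

  doac <- runif(1) < config$doac_switch_prob
  doac_date <- if (doac) d0 + round(runif(1, 5, 149)) else as.Date(NA)

  # quarterly VKA dispensing cycle anchored shortly before entry
  vka_disp <- seq(d0 - round(runif(1, 30, 170)), d5, by = 90)

  # exponential event/death times over the 150-day follow-up
  ev_dates <- as.Date(character()); ev_classes <- character()
  for (cls in names(config$event_risk_30d)) {
    lam <- config$event_risk_30d[[cls]] / WINDOW_DAYS
    if (lam > 0) {
      tt <- rexp(1, lam)
      if (tt <= 5 * WINDOW_DAYS) {
        ev_dates <- c(ev_dates, d0 + ceiling(tt))
        ev_classes <- c(ev_classes, cls)
      }
    }
  }
  lam_d <- config$death_risk_30d / WINDOW_DAYS
  if (lam_d > 0) {
    tt <- rexp(1, lam_d)
    if (tt <= 5 * WINDOW_DAYS) {
      ev_dates <- c(ev_dates, d0 + ceiling(tt))
      ev_classes <- c(ev_classes, "death")
    }
  }

  # visit schedule: log-normal gaps, median ~16 d
  visits <- as.Date(character())
  cur <- d0 - 90L
  while (cur < d5) {
    visits <- c(visits, cur)
    gap <- round(rlnorm(1, config$visit_meanlog, config$visit_sdlog))
    gap <- min(max(gap, 2), 45)
    cur <- cur + gap
  }
  nv <- length(visits)

  # latent OU process + feedback dosing
  mid <- (tr[["low"]] + tr[["high"]]) / 2
  b_i <- rnorm(1, 0, config$sigma_between)
  x <- numeric(nv)
  x[1] <- rnorm(1, 0, config$sigma_process)
  if (nv > 1) {
    gaps <- as.numeric(diff(visits))
    phi <- exp(-gaps / config$ou_tau)
    innov <- rnorm(nv - 1, 0, config$sigma_process * sqrt(1 - phi^2))
    for (j in 2:nv) x[j] <- phi[j - 1] * x[j - 1] + innov[j - 1]
  }
  in_ram <- visits >= ram_start & visits < ram_end
  obs <- mid + b_i + x + config$ramadan_inr_shift * in_ram +
    rnorm(nv, 0, config$sigma_measure)
  obs <- round(pmax(obs, 0.8), 2)

  dose <- numeric(nv)
  cur_dose <- round(rlnorm(1, log(2), 0.4), 2)
  for (j in seq_len(nv)) {
    if (obs[j] > tr[["high"]] || obs[j] < tr[["low"]]) {
      if (runif(1) < config$dose_adjust_prob) {
        step <- if (runif(1) < config$dose_step_large_prob) {
          runif(1, 0.10, 0.20)
        } else {
          runif(1, 0.02, 0.095)
        }
        cur_dose <- cur_dose * (1 + if (obs[j] > tr[["high"]]) -step else step)
      }
    }
    dose[j] <- round(cur_dose, 3)
  }

  disp_dates <- if (doac) c(vka_disp, doac_date) else vka_disp
  disp_drug <- if (doac) c(rep("vka", length(vka_disp)), "doac") else
    rep("vka", length(vka_disp))
  list(
    subject = list(
      subject_id = sid, cohort_label = config$cohort_label,
      year = as.integer(year), age_at_d0 = round(age, 1),
      sex = if (runif(1) < 0.55) "male" else "female",
      target_low = tr[["low"]], target_high = tr[["high"]]
    ),
    episodes = list(subject_id = sid, start = epi_start, end = epi_end,
                    vka_type = vka_type),
    dispensings = list(subject_id = rep(sid, length(disp_dates)),
                       date = disp_dates, drug = disp_drug),
    inr = list(
      subject_id = rep(sid, nv), date = visits, inr = obs,
      target_low = rep(tr[["low"]], nv), target_high = rep(tr[["high"]], nv),
      dose = dose
    ),
    events = list(subject_id = rep(sid, length(ev_dates)), date = ev_dates,
                  event_class = ev_classes)
  )
}

# concatenate per-subject field lists into one tibble
assemble_rows <- function(rows, field, schema) {
  cols <- names(cohort_schemas[[schema]])
  parts <- map(rows, function(r) r[[field]])
  df <- map(cols, function(cn) {
    vals <- map(parts, function(p) p[[cn]])
    tp <- cohort_schemas[[schema]][[cn]]
    v <- unlist(vals, use.names = FALSE)
    if (is.null(v)) {
      v <- switch(tp, c = character(), i = integer(), d = numeric(),
                  D = as.Date(character()))
    } else if (tp == "D") {
      v <- as.Date(v, origin = "1970-01-01")
    } else if (tp == "i") {
      v <- as.integer(v)
    }
    v
  })
  names(df) <- cols
  as_tibble(df)
}
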