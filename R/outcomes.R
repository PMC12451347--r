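#' 30-day cumulative incidence under competing risks
#'
#' Aalen-Johansen estimate of the probability of the target event class by
#' `t_eval` days, treating the other event classes (including death) as
#' competing events. With no censoring and no competing events before
#' `t_eval` the estimate reduces to events/at-risk. The confidence
#' interval is computed on the complementary log-log scale, which respects
#' the `[0, 1]` boundaries.
#'
#' @param time Days from window start to exit, one per at-risk subject.
#' @param status One of `"censor"`, `"event"` (target class) or
#'   `"competing"` per subject.
#' @param t_eval Evaluation time in days (default 30).
#' @param conf_level Confidence level (default 0.95).
#' @return A list: `estimate` (probability), `ci_low`, `ci_high`,
#'   `n_events`.
#' @export
cuminc_30d <- function(time, status, t_eval = 30, conf_level = 0.95) {
  if (length(time) == 0) {
    return(list(estimate = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, n_events = 0L))
  }
  status <- factor(as.character(status),
                   levels = c("censor", "event", "competing"))
  stopifnot(!anyNA(status), length(time) == length(status))
  n_events <- sum(status == "event" & time <= t_eval)
  if (all(status == "censor")) {
    return(list(estimate = 0, ci_low = 0, ci_high = NA_real_,
                n_events = 0L))
  }
  fit <- survival::survfit(survival::Surv(time, status) ~ 1)
  sm <- summary(fit, times = t_eval, extend = TRUE)
  col <- match("event", fit$states)
  p <- unname(sm$pstate[1, col])
  se <- unname(sm$std.err[1, col])
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (is.na(p) || p <= 0 || p >= 1 || is.na(se) || se == 0) {
    ci <- c(if (!is.na(p) && p == 0) 0 else NA_real_, NA_real_)
  } else {
    theta <- log(-log(p))
    se_theta <- se / (p * abs(log(p)))
    ci <- sort(exp(-exp(theta + c(-1, 1) * z * se_theta)))
  }
  list(estimate = p, ci_low = ci[1], ci_high = ci[2], n_events = n_events)
}

#' 30-day all-cause mortality by Kaplan-Meier
#'
#' One minus the product-limit survival estimate at `t_eval`, with a
#' Greenwood-based log-log confidence interval.
#'
#' @param time Days from window start to exit.
#' @param death Logical (or 0/1): exit by death.
#' @inheritParams cuminc_30d
#' @return A list: `estimate` (probability), `ci_low`, `ci_high`,
#'   `n_events`.
#' @export
km_mortality <- function(time, death, t_eval = 30, conf_level = 0.95) {
  if (length(time) == 0) {
    return(list(estimate = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, n_events = 0L))
  }
  death <- as.integer(death)
  n_events <- sum(death == 1 & time <= t_eval)
  fit <- survival::survfit(survival::Surv(time, death) ~ 1,
                           conf.type = "log-log",
                           conf.int = conf_level)
  sm <- summary(fit, times = t_eval, extend = TRUE)
  est <- 1 - sm$surv[1]
  lo <- 1 - sm$upper[1]
  hi <- 1 - sm$lower[1]
  if (est == 0) { lo <- 0; hi <- NA_real_ }
  list(estimate = est, ci_low = unname(lo), ci_high = unname(hi),
       n_events = n_events)
}

#' Incidence rate with exact Poisson confidence interval
#'
#' `IR = 100 * x / T` events per 100 person-years, with the exact 95%
#' interval from chi-squared quantiles:
#' lower `= qchisq(0.025, 2x) / 2 / T` (0 when `x = 0`),
#' upper `= qchisq(0.975, 2x + 2) / 2 / T`, both scaled per 100 PY.
#'
#' @param x Number of first events (non-negative integer).
#' @param t_py Person-years at risk (> 0).
#' @param conf_level Confidence level (default 0.95).
#' @return A list: `ir`, `ci_low`, `ci_high` (per 100 person-years).
#' @export
#' @examples
#' incidence_rate(10, 100)  # 10.0 (4.80-18.39) per 100 PY
incidence_rate <- function(x, t_py, conf_level = 0.95) {
  stopifnot(length(x) == 1, length(t_py) == 1)
  if (is.na(t_py) || t_py <= 0) abort("person-time must be positive")
  if (is.na(x) || x < 0 || x != round(x)) {
    abort("event count must be a non-negative integer")
  }
  alpha <- 1 - conf_level
  lo <- if (x == 0) 0 else qchisq(alpha / 2, 2 * x) / 2 / t_py
  hi <- qchisq(1 - alpha / 2, 2 * x + 2) / 2 / t_py
  list(ir = 100 * x / t_py, ci_low = 100 * lo, ci_high = 100 * hi)
}

# default outcome definitions: named list of qualifying event classes
default_outcomes <- function() {
  list(
    major_bleeding = "major_bleeding",
    arterial_te = ARTERIAL_TE_CLASSES,
    composite = COMPOSITE_CLASSES,
    all_cause_mortality = "death"
  )
}

#' Per-window incidence of clinical outcomes
#'
#' For each window and outcome definition, computes the at-risk count,
#' first-event count, person-time, incidence rate with exact Poisson CI
#' (per 100 person-years), and 30-day cumulative incidence (per 1000)
#' by the Aalen-Johansen competing-risks estimator -- or by Kaplan-Meier
#' for all-cause mortality. The clock restarts at each window start with
#' that window's at-risk set.
#'
#' @param events Event tibble (see [read_cohort_tables()]).
#' @param follow_ups Tibble from [compute_follow_up()].
#' @param window_table Per-year windows from [build_window_table()].
#' @param outcomes Named list mapping outcome names to qualifying event
#'   classes; default: major bleeding, arterial thromboembolism, the
#'   composite, and all-cause mortality.
#' @return A tibble with one row per window-outcome: `window`, `outcome`,
#'   `n_at_risk`, `n_events`, `person_years`, `ir`, `ir_low`, `ir_high`,
#'   `cuminc_per_1000`, `cuminc_low`, `cuminc_high`.
#' @export
window_incidence <- function(events, follow_ups, window_table,
                             outcomes = default_outcomes()) {
  exit_class <- follow_ups |>
    left_join(
      events |>
        group_by(.data$subject_id, .data$date) |>
        summarise(exit_classes = list(unique(.data$event_class)),
                  .groups = "drop"),
      by = c("subject_id", "exit" = "date")
    )

  out <- list()
  for (widx in sort(unique(window_table$index))) {
    joined <- join_window(exit_class, window_table, widx)
    risk <- joined |>
      filter(.data$exit > .data$win_start |
               (.data$exit == .data$win_start &
                  .data$exit_reason %in% c("clinical_event", "death")))
    n_at_risk <- nrow(risk)
    t_py <- sum(as.numeric(pmin(risk$exit, risk$win_end) - risk$win_start)) /
      DAYS_PER_YEAR
    time <- as.numeric(pmin(risk$exit, risk$win_end) - risk$win_start)
    terminal <- risk$exit < risk$win_end &
      risk$exit_reason %in% c("clinical_event", "death")
    time[terminal & time == 0] <- 0.5

    for (nm in names(outcomes)) {
      classes <- outcomes[[nm]]
      hit <- vapply(seq_len(nrow(risk)), function(i) {
        if (!terminal[i]) return(FALSE)
        cls <- risk$exit_classes[[i]]
        if (is.null(cls) && risk$exit_reason[i] == "death") cls <- "death"
        any(cls %in% classes)
      }, TRUE)
      status <- ifelse(!terminal, "censor",
                       ifelse(hit, "event", "competing"))
      if (identical(classes, "death")) {
        ci30 <- km_mortality(time, status == "event")
      } else {
        ci30 <- cuminc_30d(time, status)
      }
      x <- ci30$n_events
      irci <- if (n_at_risk > 0 && t_py > 0) incidence_rate(x, t_py) else
        list(ir = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
      out[[length(out) + 1]] <- tibble(
        window = widx, outcome = nm, n_at_risk = n_at_risk,
        n_events = x, person_years = t_py,
        ir = irci$ir, ir_low = irci$ci_low, ir_high = irci$ci_high,
        cuminc_per_1000 = 1000 * ci30$estimate,
        cuminc_low = 1000 * ci30$ci_low,
        cuminc_high = 1000 * ci30$ci_high
      )
    }
  }
  bind_rows(out)
}
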