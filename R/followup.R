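# coverage end of continuous VKA treatment from d0: episodes are
# non-overlapping and sorted; episodes starting no later than one day
# after the previous end (a VKA switch) extend coverage
vka_coverage_end <- function(starts, ends, d0) {
  ends[is.na(ends)] <- as.Date("9999-12-31")
  active <- which(starts <= d0 & ends >= d0)
  if (length(active) == 0) return(as.Date(NA))
  i <- max(active)
  cov_end <- ends[i]
  while (i < length(starts) && starts[i + 1] <= cov_end + 1L) {
    i <- i + 1L
    cov_end <- max(cov_end, ends[i])
  }
  if (cov_end >= as.Date("9999-01-01")) as.Date(NA) else cov_end
}

exit_reason_priority <- c(
  death = 1, clinical_event = 2, doac_dispensing = 3,
  doac_clinic_record = 4, vka_discontinuation = 5, window_end = 6
)

#' Compute per-subject follow-up
#'
#' Each subject enters at d0 (start of window -2) and is followed until the
#' administrative end d5 (end of window +2) or until the first of: a
#' registered DOAC dispensing, DOAC use per clinic records, discontinuation
#' of VKA therapy (end of continuous episode coverage), a clinical event of
#' interest, or death -- whichever occurs first. Events strictly before d0
#' never censor; an event on d0 itself counts (prevalent-user design).
#' Same-day ties resolve by priority death > clinical event > DOAC
#' dispensing > clinic DOAC record > discontinuation > window end.
#'
#' @param subjects,episodes,dispensings,events Cohort tibbles (see
#'   [read_cohort_tables()]).
#' @param window_table Per-year windows from [build_window_table()].
#' @return A tibble `subject_id`, `year`, `entry`, `exit`, `exit_reason`.
#' @export
compute_follow_up <- function(subjects, episodes, dispensings, events,
                              window_table) {
  bounds <- window_bounds(window_table)
  base <- subjects |>
    select("subject_id", "year") |>
    inner_join(bounds, by = "year")

  first_on_or_after <- function(df, what) {
    out <- df |>
      inner_join(select(base, "subject_id", "d0"), by = "subject_id") |>
      filter(.data$date >= .data$d0)
    if (nrow(out) == 0) {
      return(tibble(subject_id = character(),
                    "{what}" := as.Date(character())))
    }
    out |>
      group_by(.data$subject_id) |>
      summarise("{what}" := min(.data$date), .groups = "drop")
  }

  doac1 <- first_on_or_after(filter(dispensings, .data$drug == "doac"),
                             "doac_date")
  doacc1 <- first_on_or_after(filter(dispensings, .data$drug == "doac_clinic"),
                              "doac_clinic_date")
  ev1 <- first_on_or_after(
    filter(events, .data$event_class != "death"), "event_date")
  death1 <- first_on_or_after(
    filter(events, .data$event_class == "death"), "death_date")

  disc <- episodes |>
    inner_join(select(base, "subject_id", "d0"), by = "subject_id") |>
    group_by(.data$subject_id) |>
    summarise(disc_date = vka_coverage_end(.data$start, .data$end,
                                           .data$d0[1]),
              .groups = "drop")

  fu <- base |>
    left_join(doac1, by = "subject_id") |>
    left_join(doacc1, by = "subject_id") |>
    left_join(ev1, by = "subject_id") |>
    left_join(death1, by = "subject_id") |>
    left_join(disc, by = "subject_id")

  # candidate exit dates in tie-priority order, capped to [d0, d5]
  reasons <- names(exit_reason_priority)
  cand <- cbind(
    death = as.numeric(fu$death_date),
    clinical_event = as.numeric(fu$event_date),
    doac_dispensing = as.numeric(fu$doac_date),
    doac_clinic_record = as.numeric(fu$doac_clinic_date),
    vka_discontinuation = as.numeric(fu$disc_date),
    window_end = as.numeric(fu$d5)
  )
  cand <- pmin(pmax(cand, as.numeric(fu$d0)), as.numeric(fu$d5))
  cand[is.na(cand)] <- Inf
  exit_num <- do.call(pmin, as.data.frame(cand))
  pick <- max.col(-cand, ties.method = "first")
  fu |>
    mutate(exit = as.Date(exit_num, origin = "1970-01-01"),
           exit_reason = reasons[pick]) |>
    select("subject_id", "year", entry = "d0", "exit", "exit_reason")
}

# join each follow-up row to its year's window of the given index
join_window <- function(follow_ups, window_table, window_index) {
  win <- window_table |>
    filter(.data$index == window_index) |>
    select("year", win_start = "start", win_end = "end")
  inner_join(follow_ups, win, by = "year")
}

#' Number of subjects at risk at the start of a window
#'
#' A subject is at risk for a window when still under follow-up at the
#' window's start (exit strictly later than window start). Counts are
#' non-increasing from window -2 to +2.
#'
#' @param follow_ups Tibble from [compute_follow_up()].
#' @param window_table Per-year windows from [build_window_table()].
#' @param window_index Window index in -2..2.
#' @return Integer count.
#' @export
subjects_at_risk <- function(follow_ups, window_table, window_index) {
  joined <- join_window(follow_ups, window_table, window_index)
  sum(joined$exit > joined$win_start)
}

#' Person-time observed within a window
#'
#' Sum over at-risk subjects of time from window start to the earlier of
#' their exit and the window end, in years (365.25 days/year).
#'
#' @inheritParams subjects_at_risk
#' @return Person-years (numeric scalar).
#' @export
person_time <- function(follow_ups, window_table, window_index) {
  joined <- join_window(follow_ups, window_table, window_index) |>
    filter(.data$exit > .data$win_start)
  sum(as.numeric(pmin(joined$exit, joined$win_end) - joined$win_start)) /
    DAYS_PER_YEAR
}
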