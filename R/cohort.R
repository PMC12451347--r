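# run a piece of code with a private RNG stream, restoring the caller's
with_private_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# d0 anchor per subject from its calendar year (start of window -2)
subject_anchor <- function(subjects, calendar) {
  subjects |>
    left_join(select(calendar, "year", "ramadan_start"), by = "year") |>
    mutate(d0 = .data$ramadan_start - 2L * WINDOW_DAYS)
}

#' Inclusion check: adult prevalent VKA users
#'
#' A subject is included when aged >= 18 years at d0 (follow-up entry, 60
#' days before Ramadan start) and already under VKA treatment for at least
#' two months before the start of Ramadan, read as a VKA episode covering
#' the whole run-in `[d0 - 60 d, d0]`. Missing age or no episodes fail with
#' rule `"missing"`.
#'
#' @param subjects,episodes Tibbles as read by [read_cohort_tables()].
#' @param calendar Ramadan calendar tibble.
#' @return A tibble `subject_id`, `pass`, `fail_rule` (`NA` when passing;
#'   otherwise the first failing rule: `age`, `treatment<2months`,
#'   `missing`).
#' @export
check_inclusion <- function(subjects, episodes, calendar) {
  anch <- subject_anchor(subjects, calendar)
  runin <- episodes |>
    inner_join(select(anch, "subject_id", "d0"), by = "subject_id") |>
    group_by(.data$subject_id) |>
    summarise(
      covered = any(.data$start <= .data$d0 - 2L * WINDOW_DAYS &
                      (is.na(.data$end) | .data$end >= .data$d0)),
      .groups = "drop"
    )
  anch |>
    left_join(runin, by = "subject_id") |>
    mutate(
      covered = coalesce(.data$covered, FALSE),
      fail_rule = case_when(
        is.na(.data$d0) | is.na(.data$age_at_d0) ~ "missing",
        .data$age_at_d0 < 18 ~ "age",
        !.data$covered ~ "treatment<2months",
        TRUE ~ NA_character_
      ),
      pass = is.na(.data$fail_rule)
    ) |>
    select("subject_id", "pass", "fail_rule")
}

#' Exclusion check
#'
#' Applied to subjects passing inclusion, in the fixed order: (1) no VKA
#' dispensing within 6 months (183 days, half-open `[d0 - 183, d0)`) before
#' follow-up entry; (2) any DOAC dispensing in that interval; (3) VKA type
#' at d0 other than acenocoumarol or phenprocoumon; (4) missing INR target
#' range at the last measurement before d0. A subject fails at its first
#' violated rule only (flowchart convention).
#'
#' @param subjects,episodes,dispensings Tibbles as read by
#'   [read_cohort_tables()]. The subject table's `target_low`/`target_high`
#'   carry the target range at the last pre-d0 INR.
#' @param calendar Ramadan calendar tibble.
#' @return A tibble `subject_id`, `pass`, `fail_rule` (one of
#'   `no_vka_dispensing`, `doac_prior`, `vka_type`,
#'   `missing_target_range`, or `NA`).
#' @export
check_exclusion <- function(subjects, episodes, dispensings, calendar) {
  anch <- subject_anchor(subjects, calendar)
  disp6m <- dispensings |>
    inner_join(select(anch, "subject_id", "d0"), by = "subject_id") |>
    filter(.data$date >= .data$d0 - 183L, .data$date < .data$d0) |>
    group_by(.data$subject_id) |>
    summarise(has_vka = any(.data$drug == "vka"),
              has_doac = any(.data$drug == "doac"), .groups = "drop")
  type_at_d0 <- episodes |>
    inner_join(select(anch, "subject_id", "d0"), by = "subject_id") |>
    filter(.data$start <= .data$d0,
           is.na(.data$end) | .data$end >= .data$d0) |>
    group_by(.data$subject_id) |>
    slice_max(.data$start, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("subject_id", type_d0 = "vka_type")
  anch |>
    left_join(disp6m, by = "subject_id") |>
    left_join(type_at_d0, by = "subject_id") |>
    mutate(
      has_vka = coalesce(.data$has_vka, FALSE),
      has_doac = coalesce(.data$has_doac, FALSE),
      fail_rule = case_when(
        !.data$has_vka ~ "no_vka_dispensing",
        .data$has_doac ~ "doac_prior",
        is.na(.data$type_d0) |
          !.data$type_d0 %in% c("acenocoumarol", "phenprocoumon") ~ "vka_type",
        is.na(.data$target_low) | is.na(.data$target_high) ~
          "missing_target_range",
        TRUE ~ NA_character_
      ),
      pass = is.na(.data$fail_rule)
    ) |>
    select("subject_id", "pass", "fail_rule")
}

#' Apply the full inclusion/exclusion chain and tabulate the flow
#'
#' Runs [check_inclusion()] then [check_exclusion()], counting every
#' subject once at its first failing rule, and returns the flowchart of
#' counts together with the included-subject list. The filter chain is a
#' pure function of the tables: permuting input rows never changes who is
#' included.
#'
#' @inheritParams check_exclusion
#' @return A list with `flow` (tibble `stage`, `count`; first row
#'   `eligible`, last row `included`) and `included` (character vector of
#'   subject ids).
#' @export
cohort_flow <- function(subjects, episodes, dispensings, calendar) {
  inc <- check_inclusion(subjects, episodes, calendar)
  excl_stages <- c("no_vka_dispensing", "doac_prior", "vka_type",
                   "missing_target_range")
  inc_stages <- c("missing", "age", "treatment<2months")
  passed_inc <- filter(inc, .data$pass)
  exc <- check_exclusion(
    semi_join(subjects, passed_inc, by = "subject_id"),
    episodes, dispensings, calendar
  )
  fails <- bind_rows(
    filter(inc, !.data$pass) |> select("subject_id", "fail_rule"),
    filter(exc, !.data$pass) |> select("subject_id", "fail_rule")
  )
  stage_names <- c(inc_stages, excl_stages)
  counts <- table(factor(fails$fail_rule, levels = stage_names))
  included <- sort(filter(exc, .data$pass)$subject_id)
  flow <- bind_rows(
    tibble(stage = "eligible", count = nrow(subjects)),
    tibble(stage = stage_names, count = as.integer(counts)),
    tibble(stage = "included", count = length(included))
  )
  stopifnot(flow$count[flow$stage == "included"] ==
              flow$count[flow$stage == "eligible"] -
              sum(flow$count[!flow$stage %in% c("eligible", "included")]))
  list(flow = flow, included = included)
}

#' Randomly select one eligible calendar year per subject
#'
#' Subjects eligible in several calendar years contribute one
#' randomly-selected year. The draw is uniform over each subject's
#' eligible years, reproducible under `seed`, and independent of input row
#' order (subjects are processed in sorted order).
#'
#' @param eligibility Tibble with columns `subject_id`, `year`; one row per
#'   eligible subject-year, at least one row per subject.
#' @param seed Integer seed.
#' @return A tibble `subject_id`, `year` with one row per subject.
#' @export
select_one_year <- function(eligibility, seed) {
  if (nrow(eligibility) == 0) abort("empty eligibility set")
  split_years <- eligibility |>
    arrange(.data$subject_id, .data$year) |>
    group_by(.data$subject_id) |>
    summarise(years = list(as.integer(.data$year)), .groups = "drop")
  with_private_seed(seed, {
    picks <- vapply(split_years$years, function(ys) {
      if (length(ys) == 1) ys else ys[sample.int(length(ys), 1)]
    }, 1L)
  })
  tibble(subject_id = split_years$subject_id, year = as.integer(picks))
}
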