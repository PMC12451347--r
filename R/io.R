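#' Event classes
#'
#' The closed set of clinical event classes. `composite` outcomes combine
#' bleeding with venous and arterial thromboembolism; `arterial_te` groups
#' ischemic stroke, TIA, myocardial infarction and other arterial
#' thromboembolism; `death` competes with all of them.
#'
#' @format Character vectors.
#' @name event_classes
NULL

#' @rdname event_classes
#' @export
EVENT_CLASSES <- c(
  "major_bleeding", "ischemic_stroke", "tia", "myocardial_infarction",
  "other_arterial_te", "venous_te", "death"
)

#' @rdname event_classes
#' @export
ARTERIAL_TE_CLASSES <- c(
  "ischemic_stroke", "tia", "myocardial_infarction", "other_arterial_te"
)

#' @rdname event_classes
#' @export
COMPOSITE_CLASSES <- c("major_bleeding", ARTERIAL_TE_CLASSES, "venous_te")

VKA_TYPES <- c("acenocoumarol", "phenprocoumon", "other")

cohort_table_names <- c("subjects", "episodes", "dispensings", "inr", "events")

# column specs for the five canonical tables; "D" = Date
cohort_schemas <- list(
  subjects = c(subject_id = "c", cohort_label = "c", year = "i",
               age_at_d0 = "d", sex = "c", target_low = "d",
               target_high = "d"),
  episodes = c(subject_id = "c", start = "D", end = "D", vka_type = "c"),
  dispensings = c(subject_id = "c", date = "D", drug = "c"),
  inr = c(subject_id = "c", date = "D", inr = "d", target_low = "d",
          target_high = "d", dose = "d"),
  events = c(subject_id = "c", date = "D", event_class = "c")
)

coerce_schema <- function(df, schema, table) {
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("table '", table, "' is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in names(schema)) {
    df[[col]] <- switch(schema[[col]],
      c = as.character(df[[col]]),
      i = as.integer(df[[col]]),
      d = as.numeric(df[[col]]),
      D = as.Date(as.character(df[[col]]))
    )
  }
  as_tibble(df[names(schema)])
}

add_problem <- function(report, table, row, subject_id, problem) {
  bind_rows(report, tibble(
    table = table, row = as.integer(row),
    subject_id = as.character(subject_id), problem = problem
  ))
}

#' Validate the canonical cohort tables
#'
#' Checks every structural invariant the pipeline relies on: valid dates,
#' positive finite INR values, target low < high, strictly increasing
#' per-subject measurement dates (same-day duplicates are rejected),
#' non-overlapping chronologically ordered VKA episodes, event classes from
#' the closed enumeration, and drug labels in `{vka, doac}`. Validation is
#' total: every offending row appears in the report; nothing is silently
#' dropped.
#'
#' @param tables Named list with tibbles `subjects`, `episodes`,
#'   `dispensings`, `inr`, `events` (see [read_cohort_tables()] for the
#'   schemas).
#'
#' @return A tibble with columns `table`, `row` (1-based row number in the
#'   offending table), `subject_id`, `problem`; zero rows when everything
#'   is valid.
#' @export
validate_cohort_tables <- function(tables) {
  report <- tibble(table = character(), row = integer(),
                   subject_id = character(), problem = character())

  subj <- tables$subjects
  bad <- which(!is.na(subj$target_low) & !is.na(subj$target_high) &
                 subj$target_low >= subj$target_high)
  for (i in bad) {
    report <- add_problem(report, "subjects", i, subj$subject_id[i],
                          "target_low must be < target_high")
  }
  dup <- which(duplicated(subj$subject_id))
  for (i in dup) {
    report <- add_problem(report, "subjects", i, subj$subject_id[i],
                          "duplicate subject_id")
  }

  epi <- tables$episodes
  bad <- which(is.na(epi$start))
  for (i in bad) {
    report <- add_problem(report, "episodes", i, epi$subject_id[i],
                          "malformed or missing start date")
  }
  bad <- which(!epi$vka_type %in% VKA_TYPES)
  for (i in bad) {
    report <- add_problem(report, "episodes", i, epi$subject_id[i],
                          paste0("unknown vka_type '", epi$vka_type[i], "'"))
  }
  if (nrow(epi) > 0) {
    epi_idx <- tibble(.row = seq_len(nrow(epi)), epi) |>
      filter(!is.na(.data$start)) |>
      group_by(.data$subject_id) |>
      arrange(.data$start, .by_group = TRUE) |>
      mutate(prev_end = lag(.data$end), prev_start = lag(.data$start)) |>
      ungroup()
    bad <- epi_idx |>
      filter(!is.na(.data$prev_start) &
               (is.na(.data$prev_end) | .data$start < .data$prev_end))
    for (i in seq_len(nrow(bad))) {
      report <- add_problem(report, "episodes", bad$.row[i],
                            bad$subject_id[i],
                            "overlapping or unordered VKA episodes")
    }
    bad <- which(!is.na(epi$end) & epi$end <= epi$start)
    for (i in bad) {
      report <- add_problem(report, "episodes", i, epi$subject_id[i],
                            "episode end must be after start")
    }
  }

  disp <- tables$dispensings
  bad <- which(is.na(disp$date))
  for (i in bad) {
    report <- add_problem(report, "dispensings", i, disp$subject_id[i],
                          "malformed or missing date")
  }
  bad <- which(!disp$drug %in% c("vka", "doac", "doac_clinic"))
  for (i in bad) {
    report <- add_problem(report, "dispensings", i, disp$subject_id[i],
                          paste0("unknown drug '", disp$drug[i], "'"))
  }

  inr <- tables$inr
  bad <- which(is.na(inr$date))
  for (i in bad) {
    report <- add_problem(report, "inr", i, inr$subject_id[i],
                          "malformed or missing date")
  }
  bad <- which(!is.finite(inr$inr) | inr$inr <= 0)
  for (i in bad) {
    report <- add_problem(report, "inr", i, inr$subject_id[i],
                          "INR must be finite and > 0")
  }
  bad <- which(!is.na(inr$target_low) & !is.na(inr$target_high) &
                 inr$target_low >= inr$target_high)
  for (i in bad) {
    report <- add_problem(report, "inr", i, inr$subject_id[i],
                          "target_low must be < target_high")
  }
  if (nrow(inr) > 0) {
    dup <- tibble(.row = seq_len(nrow(inr)), inr) |>
      filter(!is.na(.data$date)) |>
      group_by(.data$subject_id) |>
      arrange(.data$date, .by_group = TRUE) |>
      mutate(same_day = !is.na(lag(.data$date)) & .data$date == lag(.data$date)) |>
      ungroup() |>
      filter(.data$same_day)
    for (i in seq_len(nrow(dup))) {
      report <- add_problem(report, "inr", dup$.row[i], dup$subject_id[i],
                            "same-day duplicate INR measurement")
    }
  }
  bad <- which(!is.na(inr$dose) & inr$dose < 0)
  for (i in bad) {
    report <- add_problem(report, "inr", i, inr$subject_id[i],
                          "dose must be >= 0")
  }

  ev <- tables$events
  bad <- which(is.na(ev$date))
  for (i in bad) {
    report <- add_problem(report, "events", i, ev$subject_id[i],
                          "malformed or missing date")
  }
  bad <- which(!ev$event_class %in% EVENT_CLASSES)
  for (i in bad) {
    report <- add_problem(report, "events", i, ev$subject_id[i],
                          paste0("unknown event_class '", ev$event_class[i], "'"))
  }

  report
}

#' Read the canonical cohort tables
#'
#' Reads the five long-format CSV tables describing a cohort and enforces
#' all structural invariants. Schemas (one row per record, ISO-8601 dates):
#'
#' * `subjects.csv`: `subject_id`, `cohort_label`, `year` (anchor calendar
#'   year), `age_at_d0` (years), `sex`, `target_low`, `target_high` (INR
#'   target range at the last measurement before d0; may be empty).
#' * `episodes.csv`: `subject_id`, `start`, `end` (empty = ongoing),
#'   `vka_type` (`acenocoumarol`, `phenprocoumon`, `other`).
#' * `dispensings.csv`: `subject_id`, `date`, `drug` (`vka`, `doac`, or
#'   `doac_clinic` for DOAC use known only from anticoagulation-clinic
#'   records).
#' * `inr.csv`: `subject_id`, `date`, `inr`, `target_low`, `target_high`,
#'   `dose` (recommended average daily dose in tablets/day; may be empty).
#' * `events.csv`: `subject_id`, `date`, `event_class` (see
#'   [EVENT_CLASSES]).
#'
#' @param dir Directory containing the five CSV files.
#' @param on_error `"stop"` (default) aborts with a row-level report when
#'   validation fails; `"report"` returns the tables with the report
#'   attached as attribute `"validation"`.
#'
#' @return Named list of tibbles (`subjects`, `episodes`, `dispensings`,
#'   `inr`, `events`) with typed columns; `inr`, `episodes`, `dispensings`
#'   and `events` sorted by subject and date.
#' @export
read_cohort_tables <- function(dir, on_error = c("stop", "report")) {
  on_error <- match.arg(on_error)
  paths <- file.path(dir, paste0(cohort_table_names, ".csv"))
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files) > 0) {
    abort(paste0("missing input file(s): ",
                 paste(missing_files, collapse = ", ")))
  }
  tables <- map2(paths, cohort_table_names, function(p, nm) {
    df <- readr::read_csv(p, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
    coerce_schema(df, cohort_schemas[[nm]], nm)
  })
  names(tables) <- cohort_table_names
  report <- validate_cohort_tables(tables)
  if (nrow(report) > 0 && on_error == "stop") {
    msg <- report |>
      mutate(line = paste0(.data$table, " row ", .data$row, " (subject ",
                           .data$subject_id, "): ", .data$problem)) |>
      pull("line")
    abort(paste0("invalid input rows:\n",
                 paste(utils::head(msg, 20), collapse = "\n"),
                 if (nrow(report) > 20) "\n..." else ""))
  }
  tables <- sort_cohort_tables(tables)
  if (on_error == "report") attr(tables, "validation") <- report
  tables
}

sort_cohort_tables <- function(tables) {
  tables$subjects <- arrange(tables$subjects, .data$subject_id)
  tables$episodes <- arrange(tables$episodes, .data$subject_id, .data$start)
  tables$dispensings <- arrange(tables$dispensings, .data$subject_id, .data$date)
  tables$inr <- arrange(tables$inr, .data$subject_id, .data$date)
  tables$events <- arrange(tables$events, .data$subject_id, .data$date)
  tables
}

#' Write cohort or result tables as CSV
#'
#' Writes each tibble in `tables` as `<name>.csv` under `dir` with a
#' deterministic column order (the order in the tibble) and ISO-8601 dates,
#' so a write-read-write cycle is byte-identical.
#'
#' @param tables Named list of tibbles.
#' @param dir Output directory, created if absent.
#' @return Invisibly, the paths written.
#' @export
write_cohort_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], p, na = "")
    p
  }, "")
  invisible(paths)
}
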