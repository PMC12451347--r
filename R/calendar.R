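#' Ramadan calendar
#'
#' A Ramadan calendar maps calendar years to the Gregorian start and end
#' dates of the Ramadan month. Observed Ramadan lasts 29 or 30 days; the
#' windowing functions accept 28-30 to tolerate regional sighting
#' differences. Dates are configuration, never hard-coded: supply your own
#' table or YAML file, or use the bundled default covering 2013-2019.
#'
#' @param year Integer vector of calendar years.
#' @param ramadan_start,ramadan_end `Date` vectors (or ISO-8601 strings) of
#'   the first and last day of Ramadan in each year.
#'
#' @return A tibble with columns `year`, `ramadan_start`, `ramadan_end`.
#' @export
#' @examples
#' ramadan_calendar(2016, "2016-06-06", "2016-07-05")
ramadan_calendar <- function(year, ramadan_start, ramadan_end) {
  cal <- tibble(
    year = as.integer(year),
    ramadan_start = as.Date(ramadan_start),
    ramadan_end = as.Date(ramadan_end)
  )
  dur <- as.integer(cal$ramadan_end - cal$ramadan_start) + 1L
  bad <- which(is.na(dur) | dur < 28L | dur > 30L)
  if (length(bad) > 0) {
    abort(paste0(
      "Ramadan duration must be 28-30 days; violated for year(s) ",
      paste(cal$year[bad], collapse = ", ")
    ))
  }
  if (anyDuplicated(cal$year)) abort("duplicate years in Ramadan calendar")
  arrange(cal, .data$year)
}

#' Read a Ramadan calendar from YAML
#'
#' The YAML maps years to `start`/`end` dates:
#' ```yaml
#' 2016: {start: 2016-06-06, end: 2016-07-05}
#' ```
#'
#' @param path Path to a YAML file.
#' @return A tibble as from [ramadan_calendar()].
#' @export
read_ramadan_calendar <- function(path) {
  raw <- yaml::read_yaml(path)
  ramadan_calendar(
    year = as.integer(names(raw)),
    ramadan_start = unname(vapply(raw, function(x) as.character(x$start), "")),
    ramadan_end = unname(vapply(raw, function(x) as.character(x$end), ""))
  )
}

#' Default Ramadan calendar (2013-2019)
#'
#' Gregorian dates of Ramadan for the seven study years, from the bundled
#' configuration file `inst/extdata/ramadan_calendar.yaml`.
#'
#' @return A tibble as from [ramadan_calendar()].
#' @export
default_ramadan_calendar <- function() {
  read_ramadan_calendar(
    system.file("extdata", "ramadan_calendar.yaml", package = "vkawindow",
                mustWork = TRUE)
  )
}

#' Build the five 30-day observation windows for one Ramadan
#'
#' Follow-up is anchored on the Ramadan start date S. Window 0 is the
#' Ramadan month `[S, S + 30)`; windows -2 and -1 are the two 30-day months
#' before it and windows +1 and +2 the two after, so the five windows
#' exactly partition the 150 days `[S - 60, S + 90)`. When Ramadan lasts 29
#' days the boundary after the Ramadan month falls on the observed end date
#' plus one extra day, keeping every window at exactly 30 days. All
#' intervals are half-open `[start, end)`.
#'
#' @param ramadan_start,ramadan_end `Date` (scalar): observed first and last
#'   day of Ramadan.
#'
#' @return A tibble with one row per window: `index` (-2..2, 0 = Ramadan),
#'   `start` (inclusive), `end` (exclusive).
#' @export
#' @examples
#' build_windows(as.Date("2016-06-06"), as.Date("2016-07-05"))
build_windows <- function(ramadan_start, ramadan_end) {
  ramadan_start <- as.Date(ramadan_start)
  ramadan_end <- as.Date(ramadan_end)
  stopifnot(length(ramadan_start) == 1, length(ramadan_end) == 1)
  dur <- as.integer(ramadan_end - ramadan_start) + 1L
  if (is.na(dur) || dur < 28L || dur > 30L) {
    abort("Ramadan duration must be 28-30 days")
  }
  starts <- ramadan_start + WINDOW_DAYS * (-2:2)
  tibble(
    index = -2:2,
    start = starts,
    end = starts + WINDOW_DAYS
  )
}

#' Observation windows for every calendar year
#'
#' @param calendar A Ramadan calendar tibble (see [ramadan_calendar()]).
#' @return A tibble with columns `year`, `index`, `start`, `end`; five rows
#'   per year. `d0` (follow-up entry) is the start of window -2 and `d5`
#'   (administrative end) the end of window +2.
#' @export
build_window_table <- function(calendar) {
  calendar |>
    rowwise() |>
    reframe(build_windows(.data$ramadan_start, .data$ramadan_end),
            year = .data$year) |>
    select("year", "index", "start", "end")
}

# internal: follow-up entry (d0) and administrative exit (d5) per year
window_bounds <- function(window_table) {
  window_table |>
    group_by(.data$year) |>
    summarise(d0 = min(.data$start), d5 = max(.data$end), .groups = "drop")
}
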