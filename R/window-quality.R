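#' Per-subject per-window treatment-quality metrics
#'
#' Computes every VKA treatment-quality metric for each included subject
#' and each of the five 30-day observation windows.
#'
#' A subject-window is *eligible* for the quality metrics when (a) a VKA
#' episode is active at the window start and follow-up has not yet ended
#' there, and (b) the window contains at least two INR measurements, or
#' one measurement plus at least one in the preceding 30 days (which then
#' anchors the interpolation). For window -2 the preceding 30 days lie
#' before follow-up entry; pre-entry clinic measurements may serve as the
#' borrowed anchor, reflecting that prevalent users have monitoring
#' history. When a subject-window is ineligible all quality metrics are
#' missing, never zero; measurement counts and switch flags are reported
#' regardless.
#'
#' Measurements after the follow-up exit are ignored. The target range
#' used for the Rosendaal and proportion metrics is taken from the
#' in-window measurements (falling back to the anchor measurement, then
#' the subject-level range at d0).
#'
#' @param tables Cohort tables (see [read_cohort_tables()]), restricted to
#'   included subjects.
#' @param follow_ups Tibble from [compute_follow_up()].
#' @param window_table Per-year windows from [build_window_table()].
#' @param config A [quality_config()].
#' @return A tibble with one row per subject-window: identifiers
#'   (`subject_id`, `window`), `eligible`, monitoring (`n_inr`,
#'   `median_interval_days`), INR level (`median_inr`, `mean_inr`), time
#'   in range (`ttr`, `tbr`, `tar`, percent), variability (`vgr`),
#'   measurement proportions (`prop_in`, `prop_below`, `prop_above`,
#'   `prop_ge5`, `prop_ge8`, percent), dose (`median_dose`, `mean_dose`,
#'   `dose_increase_flag`, `dose_reduction_flag`) and switches
#'   (`switched_vka_type`, `switched_doac`).
#' @export
window_quality <- function(tables, follow_ups, window_table,
                           config = quality_config()) {
  subjects <- tables$subjects
  n_subj <- nrow(subjects)
  inr_split <- split(tables$inr, tables$inr$subject_id)
  epi_split <- split(tables$episodes, tables$episodes$subject_id)
  disp_split <- split(tables$dispensings, tables$dispensings$subject_id)
  win_split <- split(window_table, window_table$year)
  fu_entry <- setNames(as.numeric(follow_ups$entry), follow_ups$subject_id)
  fu_exit <- setNames(as.numeric(follow_ups$exit), follow_ups$subject_id)

  N <- n_subj * 5L
  col_num <- function() rep(NA_real_, N)
  out <- list(
    subject_id = rep(NA_character_, N), window = rep(NA_integer_, N),
    eligible = rep(NA, N), n_inr = rep(NA_integer_, N),
    median_interval_days = col_num(), median_inr = col_num(),
    mean_inr = col_num(), ttr = col_num(), tbr = col_num(),
    tar = col_num(), vgr = col_num(), prop_in = col_num(),
    prop_below = col_num(), prop_above = col_num(), prop_ge5 = col_num(),
    prop_ge8 = col_num(), median_dose = col_num(), mean_dose = col_num(),
    dose_increase_flag = rep(NA, N), dose_reduction_flag = rep(NA, N),
    switched_vka_type = rep(NA, N), switched_doac = rep(NA, N)
  )
  pos <- 0L

  for (i in seq_len(n_subj)) {
    sid <- subjects$subject_id[i]
    wins <- win_split[[as.character(subjects$year[i])]]
    exit <- unname(fu_exit[sid])
    entry <- unname(fu_entry[sid])
    if (is.null(wins) || is.na(exit)) next

    inr <- inr_split[[sid]]
    if (is.null(inr)) {
      t <- numeric(); y <- numeric(); dose <- numeric()
      tlow <- numeric(); thigh <- numeric()
    } else {
      keep <- !is.na(inr$date) & as.numeric(inr$date) <= exit
      t <- as.numeric(inr$date)[keep]; y <- inr$inr[keep]
      dose <- inr$dose[keep]
      tlow <- inr$target_low[keep]; thigh <- inr$target_high[keep]
    }

    epi <- epi_split[[sid]]
    epi_start <- if (is.null(epi)) numeric() else as.numeric(epi$start)
    epi_end <- if (is.null(epi)) numeric() else
      ifelse(is.na(epi$end), Inf, as.numeric(epi$end))
    vka_switch <- NA_real_
    if (length(epi_start) >= 2) {
      chg <- which(epi$vka_type[-1] != epi$vka_type[-nrow(epi)])
      if (length(chg) > 0) vka_switch <- epi_start[chg[1] + 1L]
      if (!is.na(vka_switch) && vka_switch > exit) vka_switch <- NA_real_
    }
    disp <- disp_split[[sid]]
    doac_date <- NA_real_
    if (!is.null(disp)) {
      dd <- as.numeric(disp$date)[disp$drug %in% c("doac", "doac_clinic") &
                                    as.numeric(disp$date) >= entry]
      if (length(dd) > 0) doac_date <- min(dd)
    }

    for (w in 1:5) {
      pos <- pos + 1L
      ws <- as.numeric(wins$start[w]); we <- as.numeric(wins$end[w])
      out$subject_id[pos] <- sid
      out$window[pos] <- wins$index[w]
      inside <- t >= ws & t < we
      n_in <- sum(inside)
      prev_n <- sum(t >= ws - WINDOW_DAYS & t < ws)
      at_risk <- exit > ws
      active <- length(epi_start) > 0 &&
        any(epi_start <= ws & epi_end >= ws)
      eligible <- at_risk && active && (n_in >= 2 || (n_in >= 1 && prev_n >= 1))
      out$eligible[pos] <- eligible
      out$n_inr[pos] <- n_in
      out$switched_vka_type[pos] <- !is.na(vka_switch) &&
        vka_switch >= ws && vka_switch < we
      out$switched_doac[pos] <- !is.na(doac_date) &&
        doac_date >= ws && doac_date < we
      if (!eligible) next

      gaps <- diff(t)[inside[-1]]
      if (length(gaps) > 0) out$median_interval_days[pos] <- median(gaps)
      y_in <- y[inside]
      out$median_inr[pos] <- median(y_in)
      out$mean_inr[pos] <- mean(y_in)

      anchor_i <- which(t < ws)
      anchor_i <- if (length(anchor_i) > 0) max(anchor_i) else integer()
      sel <- c(anchor_i, which(inside))
      low <- first_non_na(c(tlow[inside], tlow[anchor_i],
                            subjects$target_low[i]))
      high <- first_non_na(c(thigh[inside], thigh[anchor_i],
                             subjects$target_high[i]))
      if (!is.na(low) && !is.na(high)) {
        tia <- rosendaal(t[sel], y[sel], low, high, ws, we, exit, config)
        out$ttr[pos] <- tia[["ttr"]]; out$tbr[pos] <- tia[["tbr"]]
        out$tar[pos] <- tia[["tar"]]
        pr <- inr_proportions(y_in, low, high, config)
        out$prop_in[pos] <- pr[["prop_in"]]
        out$prop_below[pos] <- pr[["prop_below"]]
        out$prop_above[pos] <- pr[["prop_above"]]
        out$prop_ge5[pos] <- pr[["prop_ge5"]]
        out$prop_ge8[pos] <- pr[["prop_ge8"]]
      }
      out$vgr[pos] <- vgr(t[sel], y[sel], ws, we, config)
      dose_in <- dose[inside]
      if (any(!is.na(dose_in))) {
        out$median_dose[pos] <- median(dose_in, na.rm = TRUE)
        out$mean_dose[pos] <- mean(dose_in, na.rm = TRUE)
      }
      if (length(sel) >= 2) {
        cls <- classify_dose_change(dose[sel][-length(sel)], dose[sel][-1])
        out$dose_increase_flag[pos] <- any(cls == "increase", na.rm = TRUE)
        out$dose_reduction_flag[pos] <- any(cls == "reduction", na.rm = TRUE)
      }
    }
  }
  as_tibble(out) |> filter(!is.na(.data$subject_id))
}

first_non_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) > 0) x[1] else NA_real_
}

#' Per-window summaries of quality metrics
#'
#' Descriptive statistics (n, mean, SD, median, IQR) of one quality metric
#' by window, over eligible subject-windows with a non-missing value.
#'
#' @param quality Tibble from [window_quality()].
#' @param metric Name of a metric column (string).
#' @return A tibble `window`, `n`, `mean`, `sd`, `median`, `q25`, `q75`.
#' @export
summarize_metric <- function(quality, metric) {
  quality |>
    filter(.data$eligible, !is.na(.data[[metric]])) |>
    group_by(.data$window) |>
    summarise(
      n = n(),
      mean = mean(.data[[metric]]),
      sd = if (n() > 1) sd(.data[[metric]]) else NA_real_,
      median = median(.data[[metric]]),
      q25 = unname(quantile(.data[[metric]], 0.25)),
      q75 = unname(quantile(.data[[metric]], 0.75)),
      .groups = "drop"
    )
}
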