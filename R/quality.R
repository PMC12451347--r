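#' Quality-metric configuration
#'
#' Conventions for the INR quality metrics that the underlying reports do
#' not pin down, exposed as explicit switches.
#'
#' @param vgr_denominator Unit of elapsed time in the variance growth
#'   rate: `"weeks"` (default, INR^2 per week) or `"days"`.
#' @param denominator Denominator of the Rosendaal time-in-range
#'   percentages: `"covered"` (default; time actually spanned by the
#'   interpolated trajectory inside the window, so no trajectory is
#'   fabricated after the last measurement) or `"full_window"` (the fixed
#'   30 days).
#' @param boundary_inclusive Logical; an INR exactly equal to a target
#'   limit counts as in range (default `TRUE`, the standard Rosendaal
#'   convention).
#' @return A named list of class `quality_config`.
#' @export
quality_config <- function(vgr_denominator = c("weeks", "days"),
                           denominator = c("covered", "full_window"),
                           boundary_inclusive = TRUE) {
  structure(
    list(
      vgr_denominator = match.arg(vgr_denominator),
      denominator = match.arg(denominator),
      boundary_inclusive = isTRUE(boundary_inclusive)
    ),
    class = "quality_config"
  )
}

in_range <- function(x, low, high, inclusive = TRUE) {
  if (inclusive) x >= low & x <= high else x > low & x < high
}

#' Rosendaal time in, below and above the target range
#'
#' Linearly interpolates the INR between consecutive measurements and
#' partitions the covered time inside the window into below-range,
#' in-range and above-range segments using exact crossing-time solutions.
#' The trajectory is clipped to `[window_start, min(window_end, exit,
#' last measurement date)]`; time before the first available anchor or
#' after the last measurement is not extrapolated. Boundary values (INR
#' exactly at a limit) count as in range.
#'
#' @param date Measurement dates (`Date` or numeric days), strictly
#'   increasing. Include the latest pre-window measurement, if any, as the
#'   interpolation anchor.
#' @param inr INR values (> 0), same length as `date`.
#' @param target_low,target_high Target range limits (low < high).
#' @param window_start,window_end Window boundaries, `[start, end)`.
#' @param exit Follow-up exit date; trajectory is not evaluated beyond it.
#' @param config A [quality_config()].
#' @return Named numeric vector `c(ttr, tbr, tar)` in percent (summing to
#'   100 under the `"covered"` denominator), or all `NA` when the covered
#'   duration is zero.
#' @export
#' @examples
#' rosendaal(c(0, 10), c(2, 4), 2, 3, 0, 10)  # crossing at day 5: 50/0/50
rosendaal <- function(date, inr, target_low, target_high,
                      window_start, window_end, exit = window_end,
                      config = quality_config()) {
  t <- as.numeric(date)
  y <- as.numeric(inr)
  stopifnot(length(t) == length(y), target_low < target_high)
  if (length(t) >= 2 && any(diff(t) <= 0)) {
    abort("measurement dates must be strictly increasing")
  }
  ws <- as.numeric(window_start)
  we <- as.numeric(window_end)
  na_out <- c(ttr = NA_real_, tbr = NA_real_, tar = NA_real_)
  if (length(t) < 2) return(na_out)
  ub <- min(we, as.numeric(exit), max(t))
  lb <- max(ws, min(t))
  if (ub - lb <= 0) return(na_out)

  below <- 0; inside <- 0; above <- 0
  for (i in seq_len(length(t) - 1)) {
    s <- max(t[i], lb); e <- min(t[i + 1], ub)
    if (e <= s) next
    y0 <- y[i]; y1 <- y[i + 1]
    if (y1 == y0) {
      zone <- if (in_range(y0, target_low, target_high,
                           config$boundary_inclusive)) "in"
              else if (y0 <= target_low) "below" else "above"
      dur <- e - s
      if (zone == "in") inside <- inside + dur
      else if (zone == "below") below <- below + dur
      else above <- above + dur
    } else {
      slope <- (y1 - y0) / (t[i + 1] - t[i])
      t_at <- function(v) t[i] + (v - y0) / slope
      cuts <- c(t_at(target_low), t_at(target_high))
      cuts <- sort(cuts[cuts > s & cuts < e])
      pts <- c(s, cuts, e)
      for (k in seq_len(length(pts) - 1)) {
        mid <- (pts[k] + pts[k + 1]) / 2
        ymid <- y0 + slope * (mid - t[i])
        dur <- pts[k + 1] - pts[k]
        if (ymid < target_low) below <- below + dur
        else if (ymid > target_high) above <- above + dur
        else inside <- inside + dur
      }
    }
  }
  denom <- switch(config$denominator,
                  covered = below + inside + above,
                  full_window = we - ws)
  if (denom <= 0) return(na_out)
  c(ttr = 100 * inside / denom, tbr = 100 * below / denom,
    tar = 100 * above / denom)
}

#' Variance growth rate (VGR) of the INR
#'
#' INR variability as the mean squared change between consecutive
#' measurements per unit elapsed time: `VGR = (1/n) * sum_i
#' (INR_i - INR_(i-1))^2 / dt_i` over the `n` consecutive pairs whose
#' later member falls inside the window, with `dt` in weeks by default.
#' The latest pre-window measurement may serve as the earlier member of
#' the first pair.
#'
#' @inheritParams rosendaal
#' @return VGR (INR^2 per week, or per day when configured); `NA` when no
#'   qualifying pair exists.
#' @export
vgr <- function(date, inr, window_start, window_end,
                config = quality_config()) {
  t <- as.numeric(date)
  y <- as.numeric(inr)
  if (length(t) >= 2 && any(diff(t) <= 0)) {
    abort("measurement dates must be strictly increasing")
  }
  if (length(t) < 2) return(NA_real_)
  ws <- as.numeric(window_start); we <- as.numeric(window_end)
  later <- t[-1]
  keep <- later >= ws & later < we
  if (!any(keep)) return(NA_real_)
  dt <- diff(t)[keep]
  dy <- diff(y)[keep]
  if (config$vgr_denominator == "weeks") dt <- dt / 7
  mean(dy^2 / dt)
}

#' Proportions of INR measurements relative to the target range
#'
#' Measurement-count proportions (in percent) of in-window INR values
#' within, below and above the target range, and at or above 5 and 8.
#' Boundary values count as within range; the 5 and 8 thresholds are
#' inclusive. Borrowed interpolation anchors from a previous window are
#' not counted here.
#'
#' @param inr INR values dated inside the window.
#' @inheritParams rosendaal
#' @return Named vector `c(prop_in, prop_below, prop_above, prop_ge5,
#'   prop_ge8)` in percent, or all `NA` when `inr` is empty.
#' @export
inr_proportions <- function(inr, target_low, target_high,
                            config = quality_config()) {
  if (length(inr) == 0) {
    return(c(prop_in = NA_real_, prop_below = NA_real_,
             prop_above = NA_real_, prop_ge5 = NA_real_,
             prop_ge8 = NA_real_))
  }
  n <- length(inr)
  inr_in <- in_range(inr, target_low, target_high, config$boundary_inclusive)
  below <- inr < target_low | (!config$boundary_inclusive & inr == target_low)
  above <- !inr_in & !below
  c(prop_in = 100 * sum(inr_in) / n,
    prop_below = 100 * sum(below) / n,
    prop_above = 100 * sum(above) / n,
    prop_ge5 = 100 * sum(inr >= 5) / n,
    prop_ge8 = 100 * sum(inr >= 8) / n)
}

#' Classify a dose change between two consecutive INR visits
#'
#' A clinically relevant dose adjustment is a change of at least 10% in
#' the recommended average daily dose between two consecutive
#' measurements; the 10% threshold is inclusive. A dose rising from zero
#' is an increase; zero to zero is no change.
#'
#' @param dose_prev,dose_next Doses (tablets/day) at two consecutive
#'   visits; vectors recycle.
#' @return Character vector in `{"none", "increase", "reduction"}`, `NA`
#'   where either dose is missing.
#' @export
#' @examples
#' classify_dose_change(2, c(1.8, 2.19, 2.2))
classify_dose_change <- function(dose_prev, dose_next) {
  n <- max(length(dose_prev), length(dose_next))
  dose_prev <- rep_len(dose_prev, n)
  dose_next <- rep_len(dose_next, n)
  rel <- (dose_next - dose_prev) / dose_prev
  out <- rep(NA_character_, n)
  ok <- !is.na(dose_prev) & !is.na(dose_next)
  out[ok & dose_prev == 0 & dose_next > 0] <- "increase"
  out[ok & dose_prev == 0 & dose_next == 0] <- "none"
  pos <- ok & dose_prev > 0
  out[pos] <- "none"
  # inclusive 10% threshold, robust to binary representation of the ratio
  eps <- 1e-9
  out[pos & rel >= 0.10 - eps] <- "increase"
  out[pos & -rel >= 0.10 - eps] <- "reduction"
  out
}

#' Monitoring frequency within a window
#'
#' @inheritParams rosendaal
#' @return Named list `n_inr` (measurements dated inside the window) and
#'   `median_interval_days` (median day gap between consecutive
#'   measurements whose later member is inside the window; `NA` when no
#'   such pair exists).
#' @export
monitoring_stats <- function(date, window_start, window_end) {
  t <- as.numeric(date)
  ws <- as.numeric(window_start); we <- as.numeric(window_end)
  inside <- t >= ws & t < we
  n_inr <- sum(inside)
  med <- NA_real_
  if (length(t) >= 2) {
    keep <- inside[-1]
    if (any(keep)) med <- median(diff(t)[keep])
  }
  list(n_inr = as.integer(n_inr), median_interval_days = med)
}
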