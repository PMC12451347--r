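#' Random-intercept period model for a quality metric
#'
#' Fits the repeated-measures comparison of one continuous quality metric
#' across the five observation windows:
#' `y_ij = beta_0 + sum_p beta_p 1[window_j = p] + b_i + e_ij`, with
#' `b_i ~ N(0, sigma_b^2)` a subject-specific random intercept and
#' `e_ij ~ N(0, sigma^2)` residual noise. The window enters as a 5-level
#' categorical variable with window -2 (two months before Ramadan) as
#' reference. Estimation is by restricted maximum likelihood (REML)
#' through [lme4::lmer()]; 95% confidence intervals use the Wald normal
#' approximation `beta_hat +/- 1.96 SE`. Subject-windows with a missing
#' value are omitted (unbalanced designs are allowed). On balanced
#' complete data the fixed effects equal the raw differences of window
#' means from the reference window.
#'
#' @param data Tibble with columns `subject_id`, `window` (integer -2..2
#'   or factor) and the metric value.
#' @param value Name of the value column (string; default `"value"`).
#' @param reference Reference window (default `-2`).
#' @param conf_level Confidence level for the Wald intervals.
#' @return An object of class `period_fit`: a list with `effects` (tibble
#'   `window`, `beta`, `se`, `ci_low`, `ci_high`, `reference`),
#'   `intercept`, `sigma_b`, `sigma`, `n_obs`, `n_subjects`, `degenerate`
#'   and (when fitted) the underlying `lme4` model as `fit`.
#' @export
fit_period_model <- function(data, value = "value", reference = -2L,
                             conf_level = 0.95) {
  df <- data |>
    transmute(subject_id = as.character(.data$subject_id),
              window = .data$window,
              value = .data[[value]]) |>
    filter(!is.na(.data$value), is.finite(.data$value))
  if (nrow(df) == 0) abort("no non-missing values to fit")
  levels_all <- sort(unique(as.integer(as.character(df$window))))
  if (!reference %in% levels_all) {
    abort("reference window absent from the data")
  }
  df$window <- factor(as.integer(as.character(df$window)),
                      levels = c(reference, setdiff(levels_all, reference)))
  z <- qnorm(1 - (1 - conf_level) / 2)
  non_ref <- setdiff(levels_all, reference)

  if (length(non_ref) == 0) {
    abort("only the reference window is present; no estimable contrasts")
  }
  effects_frame <- function(est, stderr) {
    lo <- est - z * stderr
    hi <- est + z * stderr
    tibble(
      window = c(reference, non_ref),
      beta = c(0, est),
      se = c(NA_real_, stderr),
      ci_low = c(NA_real_, lo),
      ci_high = c(NA_real_, hi),
      reference = c(TRUE, rep(FALSE, length(non_ref)))
    )
  }

  if (var(df$value) == 0 || length(unique(df$subject_id)) < 2) {
    # degenerate: no variance (or a single subject); all contrasts are the
    # raw mean differences with zero/undefined uncertainty
    means <- tapply(df$value, df$window, mean)
    beta <- as.numeric(means[as.character(non_ref)] -
                         means[as.character(reference)])
    beta[is.na(beta)] <- 0
    out <- list(
      effects = effects_frame(beta, rep(0, length(non_ref))),
      intercept = unname(means[as.character(reference)]),
      sigma_b = 0, sigma = 0,
      n_obs = nrow(df), n_subjects = length(unique(df$subject_id)),
      degenerate = TRUE, fit = NULL
    )
    class(out) <- "period_fit"
    return(out)
  }

  fit <- lme4::lmer(
    value ~ window + (1 | subject_id), data = df, REML = TRUE,
    control = lme4::lmerControl(calc.derivs = FALSE,
                                check.conv.singular = "ignore")
  )
  fe <- lme4::fixef(fit)
  se_all <- sqrt(diag(as.matrix(stats::vcov(fit))))
  idx <- paste0("window", non_ref)
  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- list(
    effects = effects_frame(unname(fe[idx]), unname(se_all[idx])),
    intercept = unname(fe[["(Intercept)"]]),
    sigma_b = vc$sdcor[vc$grp == "subject_id"][1],
    sigma = vc$sdcor[vc$grp == "Residual"][1],
    n_obs = nrow(df), n_subjects = length(unique(df$subject_id)),
    degenerate = FALSE, fit = fit
  )
  class(out) <- "period_fit"
  out
}

#' @export
print.period_fit <- function(x, ...) {
  cat("Random-intercept period model (REML)\n")
  cat(sprintf("  %d observations, %d subjects; sigma_b = %.3f, sigma = %.3f\n",
              x$n_obs, x$n_subjects, x$sigma_b, x$sigma))
  if (x$degenerate) cat("  NOTE: degenerate fit (zero variance)\n")
  print(x$effects)
  invisible(x)
}

#' Tidy a period-model fit
#'
#' @param x A `period_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per window: `window`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`, `reference`.
#' @export
tidy.period_fit <- function(x, ...) {
  x$effects |>
    rename(estimate = "beta", std.error = "se",
           conf.low = "ci_low", conf.high = "ci_high")
}

#' Model-level summary of a period-model fit
#'
#' @param x A `period_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_obs`, `n_subjects`, `sigma_b`, `sigma`,
#'   `icc`, `degenerate`.
#' @export
glance.period_fit <- function(x, ...) {
  tot <- x$sigma_b^2 + x$sigma^2
  tibble(
    n_obs = x$n_obs, n_subjects = x$n_subjects,
    sigma_b = x$sigma_b, sigma = x$sigma,
    icc = if (tot > 0) x$sigma_b^2 / tot else NA_real_,
    degenerate = x$degenerate
  )
}

#' Forest plot of period effects
#'
#' @param object A `period_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.period_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$window),
                                  y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::labs(x = "Observation window (0 = Ramadan)",
                  y = "Fixed effect vs window -2 (95% CI)") +
    ggplot2::theme_minimal()
}
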