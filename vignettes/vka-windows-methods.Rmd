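---
title: "Methods: event-anchored 30-day windows for VKA treatment quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-anchored 30-day windows for VKA treatment quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vkawindow)
library(dplyr)
```

## The design

`vkawindow` implements an event-anchored observational design for studying
vitamin K antagonist (VKA) treatment quality around the Ramadan month.
Follow-up for each subject is anchored on the Gregorian start date *S* of
Ramadan in the subject's calendar year: five contiguous 30-day windows,
indexed −2, −1, 0, +1, +2, exactly partition the 150 days
`[S − 60, S + 90)`. Window 0 is the Ramadan month. Because an observed
Ramadan lasts 29 or 30 days, the boundary after window 0 falls on the
observed end date plus one day whenever the month has 29 days; every
window is exactly 30 days, so per-window quantities are directly
comparable. All intervals in the package are half-open `[start, end)` and
dates are ISO-8601 calendar dates — the convention is ours, chosen once,
because the design itself does not dictate open/closed endpoints.

Subjects enter at `d0 = S − 60` (prevalent users, adults, under VKA
treatment for at least two months before Ramadan's start, i.e. an episode
covering `[d0 − 60, d0]`) and are followed until the administrative end
`d5 = S + 90` or until the first of: a dispensed DOAC, DOAC use in clinic
records, VKA discontinuation, a clinical event of interest, or death.
Same-day ties resolve by death > clinical event > DOAC dispensing >
clinic DOAC record > discontinuation — we prefer the outcome with analytic
consequence, since the data carry day resolution only. Subjects never
re-enter after censoring.

## Treatment-quality metrics

Within each eligible subject-window the package computes:

* **Rosendaal time in/below/above range (TTR/TBR/TAR).** The INR is
  linearly interpolated between consecutive measurements; crossing times
  of the target limits are solved exactly, so the partition of covered
  time into below/in/above segments is analytic, not gridded. Boundary
  INR values count as in range (the standard convention). The trajectory
  is clipped to `[window start, min(window end, exit, last measurement)]`
  and — by default — the *denominator is the covered time*, not the fixed
  30 days: extrapolating beyond the last measurement would fabricate
  trajectory. Both conventions are one switch away
  (`quality_config(denominator = "full_window")`), because source reports
  rarely state which they used. No maximum-gap cap is applied; with 30-day
  windows and ~16-day monitoring intervals the usual 56-day caps are
  unreachable.
* **Variance growth rate (VGR).** `VGR = (1/n) Σ (ΔINR)² / Δt` over
  consecutive measurement pairs whose later member lies in the window,
  with Δt in weeks. The exact historical constant (per week vs per day,
  `n` vs `n − 1`) is not recoverable from the literature we target, so
  the time unit is configurable (`vgr_denominator`); the default is INR²
  per week with an `n` divisor.
* **Measurement proportions** within/below/above range and ≥5 / ≥8,
  counted over measurements dated inside the window (inclusive
  thresholds).
* **Dose-change flags.** A clinically relevant adjustment is a ≥10%
  change (inclusive, with a 1e−9 guard against binary representation
  artifacts) in the recommended average daily dose between two
  consecutive visits; a window is flagged if any qualifying pair has its
  later visit in the window.
* **Monitoring statistics and switch flags** (VKA type change, DOAC
  switch).

**Eligibility.** A subject-window contributes quality metrics only when a
VKA episode is active at the window start, follow-up has not ended, and
the window holds ≥2 measurements — or ≥1 plus a measurement in the
preceding 30 days, which then anchors the interpolation. We allow the
borrowed anchor for window −2 to come from pre-entry clinic history:
prevalent users are monitored before `d0`, and the reference window would
otherwise be the *most* selected of the five, which would undermine its
role as the comparison baseline. Ineligible subject-windows carry missing
metrics, never zeros.

Repeat same-day measurements are rejected at ingest: clinics record one
result per visit, and interpolation needs strictly increasing dates.

## Outcome estimation

Each window is analysed with its own clock and its own at-risk set (all
subjects still under follow-up at the window start). Per window and
outcome the package reports first-event counts, person-time (365.25
days/year), incidence rates with the exact chi-squared (Garwood) 95%
interval — lower bound 0 when there are no events — and the 30-day
cumulative incidence by the Aalen–Johansen competing-risks estimator
(Kaplan–Meier for all-cause mortality), delegated to
`survival::survfit()`. Confidence intervals for cumulative incidences use
the complementary log-log transform, which respects the `[0, 1]`
boundaries; the reports we target do not state their CI method, and
cll-scale intervals are the boundary-respecting default in this field.
With no censoring and no competing events before day 30 the estimator
reduces to events/at-risk, which is what makes the published worked
examples arithmetically checkable.

A caveat worth recording: exact Poisson intervals are *conservative*. At
an expected count of 5 their true coverage is 0.9796 — computable by
direct enumeration — so simulation studies should not expect coverage
below 0.97 from them; this is a property of the estimator, not a defect.

## The period model

Continuous metrics are compared across windows with a linear mixed model:
`y_ij = β₀ + Σ_p β_p·1[window_j = p] + b_i + ε_ij`, `b_i ~ N(0, σ_b²)`,
`ε_ij ~ N(0, σ²)`, window −2 as reference, REML estimation via
`lme4::lmer()`, and Wald 95% intervals `β̂ ± 1.96·SE` (normal quantile,
no df correction — "Wald" without qualification). Missing subject-windows
are dropped row-wise; unbalanced panels are expected. Bounded metrics
(percentages) are modelled on the raw scale, so effects read as
percentage-point differences. On balanced complete data the REML fixed
effects equal raw window-mean differences — an exact oracle used by the
test suite. Degenerate inputs (zero variance, single subject) return a
flagged zero fit rather than an optimizer error.

## The synthetic cohort generator

No registry data ship with the package; `simulate_cohort()` generates
cohorts with the statistical structure the analysis assumes:

* visit gaps log-normal with median 16 days (IQR ≈ 10.5–24.5), the
  monitoring cadence of Dutch anticoagulation clinics;
* INR target ranges 2.0–3.0 / 2.5–3.5 / 3.0–4.0 mixed 43/47/10;
* observed INR = range midpoint + subject offset
  (`N(0, 0.30²)`) + an Ornstein–Uhlenbeck latent process (stationary SD
  0.45, correlation time 20 days) + measurement noise (`N(0, 0.20²)`),
  floored at 0.8 (physiological minimum) and rounded to two decimals.
  The marginal SD ≈ 0.577 puts ~19% of measurements above range —
  realistic for acenocoumarol-dominated populations;
* feedback dosing: an out-of-range INR triggers a dose step with
  probability 0.25, clinically relevant (≥10%) half the time, yielding a
  per-window dose-change prevalence of a few percent;
* rare exponential event hazards (composite 30-day risk ≈ 5 per 1000),
  competing death, DOAC switching and discontinuation as censoring;
* an injectable additive INR shift δ during window 0
  (`ramadan_inr_shift`; presets `"null"` with δ = 0 and
  `"ramadan-shift"` with δ = 0.3).

Each subject draws from a private RNG substream derived from the seed and
the subject index, so enlarging a cohort never reshuffles existing
subjects and output is byte-deterministic.

Because the marginal distribution of an observed INR is normal around the
range midpoint, the expected shift in the proportion of INRs above range
under a δ-shift has the closed form
`100·(Φ̄((h − δ)/s) − Φ̄(h/s))` with `h = 0.5` (half-width of every
standard range) and `s` the marginal SD
(`expected_prop_above_shift()`) — the oracle for end-to-end recovery
tests.

**What the generator does not emulate:** pharmacokinetics of specific
VKAs, dietary vitamin-K intake, INR-dependent event hazards, seasonal
monitoring patterns, or informative censoring. Passing tests demonstrate
that the *pipeline* recovers known signals injected under its own
assumptions; they say nothing about confounding or selection in real
registry data.

## Calibration conventions

For null-calibration checks (δ = 0) we compare each window's metric mean
to the reference window with a two-standard-error band using *unpaired*
standard errors. The same subjects appear in every window, so the true
sampling SD of a mean difference is smaller than the unpaired SE; with
~20 window-metric comparisons per run, the unpaired band keeps the
family-wise false-alarm rate of the whole check at a few percent without
inventing a multiplicity correction the design never specified. Wald CI
coverage of zero is assessed across all window effects of all replicates
(≥90% covering zero), the stable aggregate of a 95% criterion.

Problem sizes used by the test suite: 1000 random trajectories for the
Rosendaal oracle (1-minute integration grid, 0.05 percentage-point
tolerance), 200 replicates of 500 subjects for mixed-model recovery, ten
replicates of 3835 subjects for the end-to-end null calibration, and one
3835-subject cohort for the shift-recovery signature — the cohort size
mirroring the population the design targets.

## Disclosure masking

Count cells in `(0, 10)` display as `"<10"`; zero is not masked (it
reveals no individual). When exactly one cell in a row is masked and the
row total is publishable, the next-smallest cell in the row is
additionally masked (displayed `"Masked"`) to prevent back-calculation.
The exact co-masking algorithm used by statistical agencies is
unpublished; next-smallest-in-row is one defensible realization and is
applied uniformly.

## Known limitations

* The at-risk definition (`exit > window start`) drops a subject whose
  event falls exactly on `d0`; the incidence routines re-admit such
  subjects with a half-day event time, a convention visible only in
  day-zero edge cases.
* The VGR constant and the TTR denominator are configurable because the
  conventions differ across clinics and studies; cross-study comparisons
  should state both switches.
* The one-calendar-year random selection (`select_one_year()`) is
  exposed for multi-year eligibility tables but not exercised by the
  simulator, whose subjects carry a single anchor year.
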