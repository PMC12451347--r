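# vkawindow

Event-anchored 30-day observation windows for vitamin K antagonist (VKA)
treatment quality and clinical outcomes around the Ramadan month.

Patients on VKAs (acenocoumarol, phenprocoumon) are monitored by the INR,
and their anticoagulation quality is summarised by how much time the
interpolated INR spends inside a target range. Intermittent fasting
changes meals, hydration and medication timing, so a natural
epidemiological question is whether treatment quality and event risk
shift during the Ramadan month. `vkawindow` packages the full analysis
for that question — and for any analysis with the same event-anchored,
repeated 30-day-window shape — for biostatisticians and
pharmacoepidemiologists working with anticoagulation-clinic data:

* **Windowing** — five contiguous 30-day windows `[S − 60, S + 90)`
  anchored on the Ramadan start date `S` (window 0 = Ramadan), follow-up
  from `d0 = S − 60` until DOAC switch, VKA discontinuation, a clinical
  event, death, or the administrative end, whichever comes first.
* **Cohort filters** — adult prevalent users with a two-month treatment
  run-in; exclusions for missing VKA dispensings, prior DOAC use,
  non-standard VKA type and missing target range, with a flowchart of
  counts; random one-calendar-year selection for multi-year eligibility.
* **Quality metrics per subject-window** — Rosendaal time in/below/above
  target range by exact linear-interpolation crossing times
  (TTR/TBR/TAR), INR variance growth rate
  `VGR = (1/n) Σ (ΔINR)²/Δt` (INR²/week), measurement proportions
  in/below/above range and ≥5/≥8, clinically relevant (≥10%) dose-change
  flags, monitoring intervals, VKA/DOAC switch flags.
* **Outcomes per window** — Aalen–Johansen 30-day cumulative incidence
  under competing risks (Kaplan–Meier for all-cause mortality), exact
  chi-squared (Garwood) Poisson confidence intervals for incidence
  rates per 100 person-years.
* **Period model** — `y_ij = β₀ + Σ_p β_p·1[window_j = p] + b_i + ε_ij`
  with a subject-specific random intercept, REML via `lme4`, Wald 95%
  CIs, window −2 as reference (broom-style `tidy()`/`glance()`,
  `autoplot()`).
* **Synthetic cohorts** — a generator with log-normal visit schedules
  (median 16 d), an Ornstein–Uhlenbeck latent INR with feedback dosing,
  rare competing events, and an injectable Ramadan INR shift δ, so the
  entire pipeline runs and is testable with no data access.
* **Disclosure masking** — counts below 10 display as `"<10"`, with
  next-smallest co-masking against back-calculation.

All user-facing functions take data frames first and return tibbles, so
stages compose with the pipe.

## Worked example

Simulate a cohort with a δ = 0.3 INR shift during the Ramadan window and
run the whole pipeline:

```r
library(vkawindow)

cfg <- sim_preset("ramadan-shift", n_subjects = 800, seed = 2024)
res <- run_pipeline(cfg, metrics = c("ttr", "prop_above"))

summarize_metric(res$quality, "prop_above")
#>   window     n  mean    sd median   q25   q75
#> 1     -2   733  18.4  35.1      0     0   0
#> 2     -1   729  20.5  35.7      0     0  33.3
#> 3      0   707  37.2  42.9      0     0 100
#> 4      1   688  19.7  35.9      0     0  33.3
#> 5      2   693  20.1  35.5      0     0  33.3
```

The proportion of INRs above range jumps from ~18–20% to 37% in window 0
and only there: the injected Ramadan shift pushes measurements over the
upper target limit during the fasting month. The period model quantifies
the same signal against the pre-Ramadan reference window:

```r
res$period_effects[res$period_effects$metric == "prop_above", ]
#>   metric     window estimate std.error conf.low conf.high reference
#> 1 prop_above     -2    0         NA       NA        NA    TRUE
#> 2 prop_above     -1    2.05       1.66    -1.20      5.30 FALSE
#> 3 prop_above      0   18.8        1.68    15.6      22.1  FALSE
#> 4 prop_above      1    0.994      1.69    -2.32      4.30 FALSE
#> 5 prop_above      2    1.71       1.69    -1.59      5.01 FALSE
```

Only the Ramadan window's fixed effect (+18.8 percentage points, 95% CI
15.6–22.1) excludes zero — the other windows sit on the null, as they
should. Event counts below 10 are masked in reported incidence tables
(`res$incidence_masked`), displaying `"<10"` in line with small-cell
disclosure control.

Estimator micro-example — the exact Poisson interval for 10 events over
100 person-years:

```r
incidence_rate(10, 100)
#> $ir       10
#> $ci_low    4.795389
#> $ci_high  18.39036   # per 100 person-years
```

See `vignette("vka-windows-methods")` for the model definitions, the
generator's assumptions, and every configurable convention
(TTR denominator, VGR time unit, boundary handling).

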