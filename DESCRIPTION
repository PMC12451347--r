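Package: vkawindow
Title: Event-Anchored 30-Day Windows for Vitamin K Antagonist Treatment
    Quality and Clinical Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for event-anchored analyses of vitamin K antagonist
    (VKA) treatment quality around the Ramadan month: construction of five
    contiguous 30-day observation windows anchored on the Ramadan start
    date, per-subject per-window INR quality metrics (Rosendaal
    time-in-therapeutic-range by linear interpolation, variance growth
    rate, range proportions, clinically relevant dose-change flags),
    competing-risks cumulative incidence and exact Poisson incidence-rate
    estimation per window, and a random-intercept linear mixed model
    comparing windows. Includes a synthetic longitudinal INR cohort
    generator with feedback dosing and an injectable Ramadan-month shift,
    so the full pipeline runs end-to-end without access to registry data,
    plus small-cell disclosure masking for count tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
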