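Package: stresswear
Title: Quantifying Cardiovascular Responses to Stressors in Free-Living Wearable Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to quantify the magnitude and duration of deviations in
    motionless heart rate and heart-rate variability (RMSSD) caused by physical
    and psychological stressors in free-living wearable recordings. Computes
    motion-gated moving-block heart-rate and RMSSD metrics from beat-to-beat
    (RR) interval and accelerometer streams, builds per-user hourly-median
    circadian baselines with relative fractional differences aligned to clock
    time and to sleep/wake onset, bins event-attributable deviations around
    runs and high-stress work with double normalization, classifies run loads
    by a heart-rate-reserve score, and provides the statistical layer: linear
    spline fits to diurnal profiles, mixed-model Dunnett comparisons of
    post-event bins against the pre-event window, and Tukey comparisons of
    trapezoidal areas under the curve across run-load groups. Includes a
    seeded synthetic-cohort generator with known circadian structure and
    stressor-response kinetics for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    lme4,
    mvtnorm,
    pracma,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr,
    optparse
Config/testthat/edition: 3
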