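# stresswear

Quantifies the magnitude and duration of cardiovascular deviations caused by
physical and psychological stressors — runs and high-stress work — in
free-living wearable recordings, for researchers working with
photoplethysmography-derived beat-to-beat (RR) interval and accelerometer
streams.

The pipeline:

- **Motion-gated metrics.** Moving-block sub-sampling (5-min block, 30-s
  step) of the RR stream yields motionless heart rate
  `HR = 60000 / mean(RR)` and heart-rate variability
  `RMSSD = sqrt(mean((RR[i+1] - RR[i])^2))`, computed only where the
  accelerometer shows no motion and never during runs.
- **Circadian baseline.** Per user, hourly medians of both metrics over a
  28-day span (inclusion: ≥ 25 data days), expressed as the relative
  fractional difference (RFD) from the user's daily median, aggregated by
  clock hour and by hours from sleep/wake onset.
- **Event impact.** Around each event, 30-minute bins from 30 min before the
  start to 5 h after the end are double-normalized — time-of-day baseline
  subtracted, then the pre-event value — so each bin measures the
  event-attributable deviation (Pre ≡ 0). Runs are classified
  light/moderate/vigorous by a heart-rate-reserve zone score. Each event's
  total response is the trapezoidal area under its deviation curve.
- **Inference.** Linear-spline fits (per-segment slopes β with p-values) for
  diurnal profiles; a linear mixed model (random intercept per user) with
  Dunnett many-to-one multivariate-t contrasts of each post-event bin
  against Pre; Tukey HSD on AUC across run-load groups.

Because cohorts of this kind are proprietary, the package includes a seeded
synthetic-cohort generator (circadian sinusoids anchored to sleep, white RR
noise with `sigma = RMSSD_target/sqrt(2)`, exponential post-event kinetics,
motion bouts, whole-day missingness) with full ground truth, so every stage
is validated by parameter recovery. See the methods vignette
(`vignettes/stresswear-methods.Rmd`) for the model details and design
decisions.

## Worked example

```r
library(stresswear)

cfg <- sim_config(n_users = 3, n_days = 28,
                  events_per_user = c(run = 6, high_stress_work = 2),
                  rng_seed = 42)
cohort <- simulate_cohort_windows(cfg)   # streams -> metric windows, low memory

baseline <- hourly_medians(cohort$windows)
rfd      <- relative_fractional_difference(baseline)
bins     <- event_deviation_table(cohort$windows, cohort$events, baseline)
runs     <- bins[bins$type == "run" & bins$load != "light", ]

dunnett_vs_pre(runs, metric = "delta_hr_bpm")
tukey_auc_groups(auc_table(bins[bins$type == "run", ]), "auc_hr")
```

Output (abridged):

```
Dunnett many-to-one vs Pre: delta_hr_bpm, 13 events, 3 users (df=118)
       bin  estimate        se         t p_unadjusted   p_adjusted significant
1      Pre 0.0000000        NA        NA           NA           NA       FALSE
2     0-30 6.1208306 0.2030302 30.147389 2.837049e-57 0.000000e+00        TRUE
3    30-60 4.4719309 0.2030302 22.025939 1.281629e-43 0.000000e+00        TRUE
...
8  180-210 0.9303541 0.2030302  4.582343 1.149870e-05 6.666667e-05        TRUE
9  210-240 0.6592013 0.2030302  3.246814 1.519503e-03 1.450000e-02        TRUE
10 240-270 0.4948645 0.2030302  2.437394 1.628566e-02 1.314333e-01       FALSE
11 270-300 0.3258046 0.2030302  1.604710 1.112308e-01 6.027500e-01       FALSE

Tukey HSD on auc_hr across run loads (per-user means)
           contrast estimate      lwr      upr   p_adjusted significant
1    moderate-light 455.6444 394.1333 517.1555 1.264236e-06        TRUE
2    vigorous-light 684.7831 623.2721 746.2942 1.745749e-07        TRUE
3 vigorous-moderate 229.1387 167.6277 290.6498 6.640346e-05        TRUE
```

Reading it: after the moderate and vigorous runs, motionless HR in the first
half hour is elevated by about 6 bpm and the elevation decays over the
following bins; the simulated response remains detectable through the
210–240-min bin (adjusted p < 0.05) and is lost in the noise afterwards.
The Tukey table compares total post-run HR response (AUC, bpm·min) between
run loads; all three contrasts are positive and significant, recovering the
simulated dose-response ordering.

A one-command pipeline over a YAML config (writes `windows.csv`,
`baseline.csv`, `rfd_profiles.csv`, `event_bins.csv`, `event_auc.csv`,
`spline_fits.csv`, `dunnett.csv`, `tukey.csv`, `summary.txt` and a
`manifest.json` with digests) is available as `run_pipeline(config, out_dir)`
or via the thin CLI at `inst/scripts/stresswear`.

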