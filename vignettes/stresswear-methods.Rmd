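---
title: "Quantifying cardiovascular stress responses from wearable data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cardiovascular stress responses from wearable data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stresswear)
```

## The problem

Physical and psychological stressors leave a cardiovascular signature:
heart rate (HR) rises and vagally mediated heart-rate variability (HRV)
falls, during the stressor and for hours afterwards. Wrist wearables that
record beat-to-beat (RR) intervals by photoplethysmography make it possible
to measure that signature in free-living conditions — but only if three
confounds are handled: optical pulse signals are unreliable under wrist
motion, HR and HRV follow strong circadian rhythms, and individuals differ
widely in their resting levels.

`stresswear` implements an analysis pipeline that addresses each in turn:

1. **Motion-gated metrics.** HR and RMSSD are computed by moving-block
   sub-sampling — a 5-minute block advanced every 30 seconds — and a block
   only yields values when its accelerometer samples show no motion
   (`HR_motionless`). Blocks overlapping a logged run are discarded outright,
   because wrist cadence corrupts the pulse signal regardless of what the
   gate sees.
2. **Circadian baseline.** For each user, the median `HR_motionless` and
   RMSSD are taken per clock hour over (at most) 28 days; users need at
   least 25 days of data in that span. Each hour is then expressed relative
   to the user's daily median — the *relative fractional difference* (RFD) —
   which removes between-user level differences and exposes the rhythm.
   Profiles are also aggregated by hours from sleep onset and from wake
   onset, since the rhythm is anchored to the sleep schedule rather than to
   clock time.
3. **Event-aligned deviations.** Around each logged run or high-stress work
   event, metrics are aggregated into the 30 minutes before the start
   ("Pre"), the event itself ("During", meaningful only for sedentary
   stressors), and ten 30-minute bins covering the 5 hours after the end.
   Each bin mean is normalized twice: first the user's hourly median for the
   bin's clock hour is subtracted, then the Pre value, so a bin measures the
   event-attributable deviation and Pre is 0 by construction.
4. **Inference.** Diurnal RFD profiles are summarized by continuous
   piecewise-linear (linear spline) fits with per-segment slopes and
   p-values. Post-event bins are compared against Pre with a linear mixed
   model (random intercept per user) and Dunnett many-to-one multivariate-t
   contrasts. Total response magnitude per event is the trapezoidal area
   under the deviation curve (baseline 0), compared across run-load groups
   with Tukey's HSD.

Because raw cohorts of this kind are proprietary, the package ships a
synthetic-data generator with known ground truth; every pipeline stage is
validated by parameter recovery on simulated cohorts.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes — not
the physics of photoplethysmography.

**Circadian curves.** Instantaneous HR and the RMSSD target follow
single-harmonic sinusoids phased to the sleep schedule: HR has its trough at
mid-sleep and the RMSSD curve peaks one hour before habitual wake. A single
harmonic is the simplest shape that reproduces the qualitative diurnal
pattern of resting HR and HRV; the analysis itself never assumes this
functional form, so recovery tests are meaningful.

**Beat generation.** Beats are event-driven: beat *i* falls at
`t[i-1] + rr[i]/1000` with `rr = 60000/HR(t) + eps`. The defining update
evaluates HR at the new beat's own time, which is circular; since HR changes
by under 1e-4 bpm within one beat, the generator evaluates the curves at the
previous beat time (the sinusoids are tabulated on a 5-s grid with linear
interpolation, an approximation error of order 1e-7 bpm). The noise `eps` is
white Gaussian with SD `RMSSD_target(t)/sqrt(2)`: for independent
successive-difference noise, `E[(eps[i+1]-eps[i])^2] = 2*sigma^2`, so this
scaling makes the theoretical RMSSD equal the target exactly. Autocorrelated
HRV structure is deliberately out of scope. A zero RMSSD target (used only
in tests) produces the noiseless stream `60000/HR(t)` exactly.

**Events.** Runs and high-stress work are placed at most one per day,
during waking hours. A run raises HR during the event to a configurable
fraction of heart-rate reserve (default 45/65/85% for light/moderate/
vigorous) — those samples are motion-gated out of the metrics but drive the
load classifier. After the event end, HR carries an offset
`+delta_hr * exp(-(t-end)/tau_hr)` and the RMSSD target an offset
`-delta_hrv * exp(-(t-end)/tau_hrv)`, floored at 1 ms to stay
physiological. High-stress work applies its (smaller) offsets during the
event as well — it is sedentary, so motionless windows exist during it.
Default kinetics (moderate run: +6 bpm with tau 90 min, -10 ms with tau
150 min; scaled up/down for vigorous/light) were chosen once so that
detectable HR elevation persists roughly 3 h and HRV suppression 5 h or
more after a moderate or vigorous run, the qualitative pattern expected
after endurance exercise; they are configuration, not estimates.

**Motion.** The accelerometer magnitude sits at 1 g with 0.005 g noise,
plus short fidget bouts at a Poisson rate (default 2/h) and saturated
motion over the full span of every run, so run windows always fail the
gate.

**Missingness and heterogeneity.** Whole days drop out independently
(default probability 0.05), mirroring how wearables actually lose data
(device off the wrist); intra-day gaps are not modeled. Users differ in
mesor (HR: normal, SD 4 bpm; RMSSD: lognormal, SD 0.15) but share the
fractional circadian amplitude, keeping the RFD estimand common across
users.

**Reproducibility.** All draws derive from one root seed through a fixed
splitting scheme (cohort-level plan: stream 0; per-user RR and
accelerometer streams: streams 1 and 2 keyed by user index), so any stream
can be regenerated in isolation and identical configs give byte-identical
cohorts.

## Tunable parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `step_s`, `block_s` | 30, 300 | s | moving-block sub-sampling geometry |
| `threshold_g` | 0.05 | g | deviation from 1 g that counts as motion |
| `max_exceed_frac` | 0 | — | tolerated fraction of moving samples (0 = all-or-nothing) |
| `min_beats` | 100 | beats | floor per 5-min window (~20 bpm), forbids degenerate RMSSD |
| `span_days`, `min_days` | 28, 25 | days | baseline span and inclusion rule |
| `min_windows_per_hour` | 3 | windows | below this an hourly median is flagged missing |
| `rfd mode` | hourly/daily | — | RFD direction (see below) |
| `n_post_bins` | 10 | bins | 5 h of 30-min post-event bins |
| `hr_max_bpm` | 190 | bpm | heart-rate-reserve scale for run loads |
| `alpha` | 0.05 | — | significance level throughout |

The motion threshold is a declared free parameter: commercial artifact
criteria are unpublished, and no attempt is made to reconstruct one. The
load-score cut-offs (60/180 on the zone-weighted minutes score) are
likewise a documented surrogate calibrated so that the generator's
easy/steady/hard runs land in the intended classes; they claim nothing
about any proprietary algorithm.

## Design choices where the design was open

**RFD direction.** One natural reading of "relative fractional difference"
divides the daily median by the hourly median; the other divides hourly by
daily. The two are reciprocal and the first inverts the plotted rhythm
(an hour with elevated HR would read below 1). The default is
`hourly_over_daily`, which keeps rhythms upright; the verbatim alternative
is available via `mode = "daily_over_hourly"` and both are tested.

**Deviation sign.** Deviations are `post - pre`, so post-exercise HR
elevation is positive and HRV suppression negative, matching how
dose-response figures are conventionally read. The reverse order would flip
every sign.

**Post-event clock.** Post-event time runs from the event *end* — recovery
kinetics start when the stressor stops — and bins with no valid windows are
missing, never zero. Events whose 5-hour post window overlaps another
logged event of the same user are excluded by default (flag to disable);
events whose post window runs into sleep keep their sleep windows, which
are motionless and valid.

**Bin normalization.** A 30-min bin is normalized against the hourly median
of the clock hour containing the bin *center*, with no interpolation — the
baseline has hourly resolution and pretending otherwise would manufacture
precision.

**Pooling.** Hourly medians pool all valid windows across days before the
median is taken (a per-day-first variant exists as an option); offsets for
the sleep/wake-aligned profiles are computed per sleep episode, naps are
out of scope, and a window exactly at onset belongs to bin +0.5 (half-open
`[k, k+1)` binning).

**Mixed model.** The Dunnett layer fits `deviation ~ bin` with a random
intercept per user — the minimal structure honouring repeated events per
user; events nested within users are not modeled. Because Pre is
identically 0 by construction, the model is fit on the During/post bins and
each contrast tests a bin mean against 0, with the multivariate-t
correction taken over all bins jointly using the fixed-effect covariance.
Degrees of freedom use a containment approximation
(`N - n_bins - n_users + 1`). Equicoordinate probabilities are computed by
Monte Carlo (6e4 draws of the max-|T| null), which prices every contrast
from one sample with standard error about 1e-3; an independent
cross-check against `multcomp`'s single-step machinery is part of the test
suite. The shared Pre value induces positive correlation between bins that
the bin-level model does not exploit, so the familywise test is mildly
conservative — acceptable for an error-rate guarantee.

**Tukey on AUC.** Per-event AUCs are averaged within user and load group
first (one value per user per group) to avoid pseudo-replication; a raw
per-event mode exists. With two groups the procedure reduces exactly to the
pooled two-sample t-test, which the suite verifies.

**HR estimator.** Window HR is `60000/mean(rr)` — beats per elapsed time,
the conventional epoch estimator — not the mean of instantaneous `60000/rr`
rates; the two differ whenever RR varies within a window and the test suite
pins the distinction.

## Numerical choices

- Window membership is half-open `[center - 150 s, center + 150 s)` on beat
  time, so adjacent blocks never double-count a beat; successive-difference
  pairs must lie entirely inside the block.
- Per-window sums use an O(n) two-pointer sweep in compiled code; agreement
  with a naive per-window recomputation to 1e-9 relative error is an
  acceptance property.
- The trapezoidal AUC spans the surviving bin centers (15, 45, ..., 285 min),
  so missing interior bins are bridged linearly; fewer than two non-missing
  bins make the AUC undefined and exclude the event.
- Spline fits use the truncated-power basis, which enforces continuity at
  the knots by construction; segment slopes are linear combinations of
  coefficients with standard errors from the OLS covariance. Default knots
  sit at profile bin centers (clock-hour HR: 0.5, 4.5, 13.5, 19.5, 23.5 h).
- Degenerate inputs fail loudly and specifically: fewer than 2 RR intervals
  (RMSSD), an empty accelerometer block, an empty spline segment, fewer
  than 2 users (Dunnett), fewer than 2 groups (Tukey). Events without valid
  Pre windows are excluded with a logged reason rather than erroring the
  run.

## What the simulation study does and does not show

Validation problem sizes were chosen to exercise each property at useful
statistical resolution: circadian slope recovery on 20 seeds of 50-user,
28-day cohorts (the fitted spline slopes are compared with the same
projection applied to the analytic rhythm, within 2 standard errors);
event-duration recovery on ~500 injected moderate runs across 50 users;
familywise error on 500 replicate 4-user null cohorts (4-day span with the
inclusion rule scaled to it); dose-response ordering on 50 replicates of a
three-group AUC design. The accelerometer runs at 0.2 Hz in the large
simulation studies — gating behaviour is unchanged since fidget bouts last
at least 5 s.

Passing these tests shows the pipeline recovers what the generator put in:
sinusoidal rhythms, exponential recovery kinetics, white RR noise, clean
event logs, whole-day missingness. Real data differ in ways the generator
deliberately omits — ectopic beats and detector error, autocorrelated HRV,
naps and shift work, mislabeled or unlogged events, intra-day gaps — so
test results bound implementation correctness, not field validity.

## Known limitations

- Time is "seconds from cohort epoch" with fixed 24-h days: no time zones,
  no DST, no calendar.
- One sleep episode per day; nap handling is out of scope.
- Frequency-domain HRV, SDNN, beat correction and artifact interpolation
  are out of scope (RMSSD only).
- The run-load surrogate is a documented stand-in, not a reconstruction of
  any commercial score.
- The mixed model ignores the bin-bin correlation induced by Pre
  subtraction (conservative, see above).
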