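#' Root-mean-square of successive differences (RMSSD)
#'
#' The time-domain heart-rate-variability statistic:
#' `sqrt(mean((rr[i+1] - rr[i])^2))` over consecutive RR intervals.
#'
#' @param rr_ms Numeric vector of RR intervals, milliseconds (>= 2 values).
#' @return RMSSD in milliseconds.
#' @export
#' @examples
#' rmssd(c(800, 810, 790, 805))
rmssd <- function(rr_ms) {
  if (length(rr_ms) < 2)
    stop("insufficient data: RMSSD needs at least 2 RR intervals")
  sqrt(mean(diff(rr_ms)^2))
}

#' Mean heart rate of an RR sequence
#'
#' Count-based epoch estimator: `60000 / mean(rr_ms)`, i.e. beats per unit of
#' elapsed time — not the mean of instantaneous `60000/rr` rates.
#'
#' @param rr_ms Numeric vector of RR intervals, milliseconds (>= 1 value).
#' @return Heart rate in bpm.
#' @export
#' @examples
#' mean_hr(c(600, 1200))  # 66.67, not 75
mean_hr <- function(rr_ms) {
  if (length(rr_ms) < 1)
    stop("insufficient data: mean HR needs at least 1 RR interval")
  60000 / mean(rr_ms)
}

#' Is an accelerometer block motionless?
#'
#' A block is motionless iff the fraction of samples deviating from the rest
#' level by more than `threshold_g` is at most `max_exceed_frac` (default 0:
#' all-or-nothing gating).
#'
#' @param motion_block Numeric vector of magnitudes (g), or a data.frame with
#'   a `magnitude_g` column.
#' @param threshold_g Deviation from `rest_g` that counts as motion.
#' @param max_exceed_frac Tolerated fraction of moving samples.
#' @param rest_g Rest level (1 g gravity by default).
#' @return Logical.
#' @export
is_motionless <- function(motion_block, threshold_g, max_exceed_frac = 0,
                          rest_g = 1) {
  if (is.data.frame(motion_block)) motion_block <- motion_block$magnitude_g
  if (length(motion_block) < 1)
    stop("insufficient data: empty accelerometer block")
  mean(abs(motion_block - rest_g) > threshold_g) <= max_exceed_frac
}

#' Moving-block metric windows with motion gating
#'
#' Tiles the recording with 5-minute blocks advanced every 30 seconds and
#' computes, per window, the motionless heart rate (`mean_hr`) and RMSSD from
#' the beats whose time falls in `[center - block/2, center + block/2)`
#' (half-open, so no beat is counted twice by adjacent blocks). A window is
#' `valid` iff its accelerometer block is motionless, it holds at least
#' `min_beats` beats, its HR lies in the physiological range, and it does not
#' overlap a logged run (cardiovascular metrics are not computed during runs:
#' wrist motion corrupts the optical pulse signal). Invalid windows keep
#' their flags but carry `NA` metrics.
#'
#' @param beats Data frame with `beat_time_s`, `rr_ms`.
#' @param motion Data frame with `sample_time_s`, `magnitude_g`.
#' @param events Optional event table; windows overlapping `type == "run"`
#'   intervals are invalidated regardless of the accelerometer.
#' @param step_s Step between window centers (default 30 s).
#' @param block_s Window length (default 300 s).
#' @param threshold_g,max_exceed_frac,rest_g Motion gate, see
#'   [is_motionless()].
#' @param min_beats Minimum beats per window (default 100, ~20 bpm floor).
#' @param hr_range Physiological HR range, bpm.
#' @return `sw_windows` data frame: `center_time_s`, `hr_motionless_bpm`,
#'   `rmssd_ms`, `n_beats`, `motionless`, `valid`. Empty streams give an
#'   empty frame.
#' @export
compute_metric_windows <- function(beats, motion, events = NULL,
                                   step_s = 30, block_s = 300,
                                   threshold_g = 0.05, max_exceed_frac = 0,
                                   rest_g = 1, min_beats = 100,
                                   hr_range = c(25, 220)) {
  empty <- data.frame(center_time_s = numeric(0), hr_motionless_bpm = numeric(0),
                      rmssd_ms = numeric(0), n_beats = integer(0),
                      motionless = logical(0), valid = logical(0))
  class(empty) <- c("sw_windows", "data.frame")
  if (is.null(beats) || nrow(beats) == 0) return(empty)

  bt <- beats$beat_time_s
  rr <- beats$rr_ms
  half <- block_s / 2
  first <- ceiling((bt[1] + half) / step_s) * step_s
  last <- floor((bt[length(bt)] - half) / step_s) * step_s
  if (last < first) return(empty)
  centers <- seq(first, last, by = step_s)
  lo <- centers - half
  hi <- centers + half

  # beat membership: half-open [lo, hi) on beat time
  bs <- cpp_window_beat_stats(bt, rr, lo, hi)
  n_beats <- bs$n_beats
  hr <- ifelse(n_beats > 0, 60000 / (bs$sum_rr / n_beats), NA_real_)
  rmssd_w <- ifelse(bs$n_d > 0, sqrt(pmax(bs$sum_d2, 0) / pmax(bs$n_d, 1L)),
                    NA_real_)

  # motion gate over the same half-open block
  if (!is.null(motion) && nrow(motion) > 0) {
    mc <- cpp_window_motion_counts(motion$sample_time_s,
                                   abs(motion$magnitude_g - rest_g) > threshold_g,
                                   lo, hi)
    motionless <- ifelse(mc$n_samples > 0,
                         mc$n_exceed / mc$n_samples <= max_exceed_frac, NA)
  } else {
    motionless <- rep(NA, length(centers))
  }

  in_run <- rep(FALSE, length(centers))
  if (!is.null(events) && nrow(events) > 0) {
    runs <- events[events$type == "run", , drop = FALSE]
    for (i in seq_len(nrow(runs)))
      in_run <- in_run | (hi > runs$start_s[i] & lo < runs$end_s[i])
  }

  valid <- !is.na(motionless) & motionless & n_beats >= min_beats &
    !is.na(hr) & hr >= hr_range[1] & hr <= hr_range[2] & !in_run
  hr[!valid] <- NA_real_
  rmssd_w[!valid] <- NA_real_

  out <- data.frame(center_time_s = centers, hr_motionless_bpm = hr,
                    rmssd_ms = rmssd_w, n_beats = n_beats,
                    motionless = as.logical(motionless), valid = valid)
  class(out) <- c("sw_windows", "data.frame")
  out
}
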