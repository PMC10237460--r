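# Shared fixtures and independent oracles, built in code.

flat_profile <- function(hr = 60, hrv = 0, hr_amp = 0, hrv_amp = 0,
                         hr_peak_h = 15, hrv_peak_h = 6) {
  list(hr_mesor_bpm = hr, hr_amp_bpm = hr_amp, hr_peak_h = hr_peak_h,
       hrv_mesor_ms = hrv, hrv_amp_ms = hrv_amp, hrv_peak_h = hrv_peak_h)
}

# deterministic constant-rate beat stream built directly (not via the simulator)
const_beats <- function(hr_bpm, t0, t_end) {
  rr <- 60000 / hr_bpm
  times <- seq(t0 + rr / 1000, t_end, by = rr / 1000)
  data.frame(beat_time_s = times, rr_ms = rr)
}

quiet_motion <- function(t0, t_end, rate_hz = 1, rest_g = 1) {
  data.frame(sample_time_s = seq(t0, t_end - 1 / rate_hz, by = 1 / rate_hz),
             magnitude_g = rest_g)
}

# literal per-window oracle: subsets beats/motion per window and applies the
# defining formulas directly, no incremental reuse
naive_windows <- function(beats, motion, step_s = 30, block_s = 300,
                          threshold_g = 0.05, max_exceed_frac = 0, rest_g = 1,
                          min_beats = 100, hr_range = c(25, 220)) {
  bt <- beats$beat_time_s
  half <- block_s / 2
  first <- ceiling((bt[1] + half) / step_s) * step_s
  last <- floor((bt[length(bt)] - half) / step_s) * step_s
  centers <- seq(first, last, by = step_s)
  out <- data.frame(center_time_s = centers, hr_motionless_bpm = NA_real_,
                    rmssd_ms = NA_real_, n_beats = 0L, motionless = NA,
                    valid = FALSE)
  for (k in seq_along(centers)) {
    lo <- centers[k] - half
    hi <- centers[k] + half
    inb <- which(bt >= lo & bt < hi)
    out$n_beats[k] <- length(inb)
    ms <- motion$sample_time_s >= lo & motion$sample_time_s < hi
    if (any(ms))
      out$motionless[k] <-
        mean(abs(motion$magnitude_g[ms] - rest_g) > threshold_g) <= max_exceed_frac
    if (length(inb) >= 1) {
      hr <- 60000 / mean(beats$rr_ms[inb])
      rms <- if (length(inb) >= 2) sqrt(mean(diff(beats$rr_ms[inb])^2)) else NA
      ok <- isTRUE(out$motionless[k]) && length(inb) >= min_beats &&
        hr >= hr_range[1] && hr <= hr_range[2]
      out$valid[k] <- ok
      if (ok) {
        out$hr_motionless_bpm[k] <- hr
        out$rmssd_ms[k] <- rms
      }
    }
  }
  out
}

# windows table for a synthetic user with known constant metrics
windows_frame <- function(user_id, centers, hr, hrv, valid = TRUE) {
  data.frame(user_id = user_id, center_time_s = centers,
             hr_motionless_bpm = hr, rmssd_ms = hrv,
             n_beats = 300L, motionless = TRUE, valid = valid,
             stringsAsFactors = FALSE)
}
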