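#' Simulation configuration for a synthetic wearable cohort
#'
#' Assembles and validates the parameters of the synthetic-cohort generator.
#' The generator emulates the statistical structure the downstream analysis
#' assumes: circadian rhythms in heart rate (HR) and heart-rate variability
#' (RMSSD) anchored to the sleep schedule, motion bouts, runs of
#' light/moderate/vigorous load, and high-stress work events with post-event
#' HR elevation and HRV suppression.
#'
#' @param n_users Number of simulated users.
#' @param n_days Days per user (default 28, the span of the analysis window).
#' @param accel_rate_hz Accelerometer sampling rate, samples/s.
#' @param hr_mesor_bpm Mean (mesor) of the circadian resting-HR sinusoid, bpm.
#' @param hr_circ_amplitude_frac Circadian HR amplitude as a fraction of the
#'   mesor (e.g. 0.05 for a 5-percent swing).
#' @param hrv_mesor_ms Mean RMSSD target, ms.
#' @param hrv_circ_amplitude_frac Circadian RMSSD amplitude, fraction of mesor.
#' @param hr_between_user_sd_bpm SD of per-user HR mesors around
#'   `hr_mesor_bpm` (0 = identical users).
#' @param hrv_between_user_sd_frac SD of the per-user log RMSSD mesor
#'   (lognormal between-user scatter; 0 = identical users).
#' @param sleep_onset_hour Clock hour of habitual sleep onset (0-24).
#' @param sleep_duration_h Sleep duration, hours.
#' @param sleep_jitter_sd_h Night-to-night SD of sleep onset, hours.
#' @param events_per_user Named counts of logged events per user, names among
#'   `"run"` and `"high_stress_work"`. At most one event is placed per day.
#' @param run_load_mix Named probabilities over `c("light","moderate","vigorous")`
#'   used to assign run loads.
#' @param response_params Per event type (and per run load) the injected
#'   response: `delta_hr_bpm` and `delta_hrv_ms` (post-event offsets at the
#'   event end), `tau_hr_min` / `tau_hrv_min` (exponential recovery time
#'   constants), `duration_min`, and for runs `during_frac_hrr` (the
#'   during-run heart-rate-reserve fraction). See Details.
#' @param hr_max_bpm Maximal HR used to place during-run HR on the
#'   heart-rate-reserve scale.
#' @param missing_day_prob Probability that a whole day of data is dropped.
#' @param fidget_rate_per_h Poisson rate of short spontaneous motion bouts.
#' @param accel_rest_g Resting accelerometer magnitude (gravity), g.
#' @param accel_rest_noise_g SD of resting accelerometer noise, g.
#' @param motion_threshold_g Deviation from rest level that flags motion, g.
#' @param rng_seed Root seed; all random draws derive from it via the
#'   documented stream-splitting scheme (see [simulate_cohort()]).
#'
#' @details
#' Circadian phases are anchored to the sleep schedule: the HR sinusoid has
#' its trough at mid-sleep and the RMSSD sinusoid peaks one hour before wake,
#' reproducing the qualitative diurnal pattern of resting HR and HRV.
#' Successive-difference noise is white, so a noise SD of
#' `rmssd_target / sqrt(2)` yields exactly the target RMSSD in expectation.
#'
#' Default response kinetics: a moderate run injects +6 bpm decaying with a
#' 90-min time constant and suppresses RMSSD by 10 ms with a 150-min time
#' constant, so that detectable HR elevation persists roughly 3-3.5 h and HRV
#' suppression 5 h or more, the qualitative dose-response pattern expected
#' after moderate/vigorous exercise. High-stress work applies its offset
#' during the event as well as after it.
#'
#' @return A validated `sw_sim_config` object (a named list).
#' @seealso [simulate_cohort()]
#' @export
#' @examples
#' cfg <- sim_config(n_users = 2, n_days = 5, events_per_user = c(run = 2))
#' cfg$n_users
sim_config <- function(n_users = 10,
                       n_days = 28,
                       accel_rate_hz = 1,
                       hr_mesor_bpm = 60,
                       hr_circ_amplitude_frac = 0.05,
                       hrv_mesor_ms = 50,
                       hrv_circ_amplitude_frac = 0.25,
                       hr_between_user_sd_bpm = 4,
                       hrv_between_user_sd_frac = 0.15,
                       sleep_onset_hour = 23,
                       sleep_duration_h = 8,
                       sleep_jitter_sd_h = 0.25,
                       events_per_user = c(run = 0, high_stress_work = 0),
                       run_load_mix = c(light = 1/3, moderate = 1/3, vigorous = 1/3),
                       response_params = default_response_params(),
                       hr_max_bpm = 190,
                       missing_day_prob = 0.05,
                       fidget_rate_per_h = 2,
                       accel_rest_g = 1,
                       accel_rest_noise_g = 0.005,
                       motion_threshold_g = 0.05,
                       rng_seed = 1L) {
  cfg <- list(
    n_users = n_users, n_days = n_days, accel_rate_hz = accel_rate_hz,
    hr_mesor_bpm = hr_mesor_bpm, hr_circ_amplitude_frac = hr_circ_amplitude_frac,
    hrv_mesor_ms = hrv_mesor_ms, hrv_circ_amplitude_frac = hrv_circ_amplitude_frac,
    hr_between_user_sd_bpm = hr_between_user_sd_bpm,
    hrv_between_user_sd_frac = hrv_between_user_sd_frac,
    sleep_onset_hour = sleep_onset_hour, sleep_duration_h = sleep_duration_h,
    sleep_jitter_sd_h = sleep_jitter_sd_h,
    events_per_user = events_per_user, run_load_mix = run_load_mix,
    response_params = response_params, hr_max_bpm = hr_max_bpm,
    missing_day_prob = missing_day_prob, fidget_rate_per_h = fidget_rate_per_h,
    accel_rest_g = accel_rest_g, accel_rest_noise_g = accel_rest_noise_g,
    motion_threshold_g = motion_threshold_g,
    rng_seed = as.integer(rng_seed))
  validate_sim_config(cfg)
  class(cfg) <- "sw_sim_config"
  cfg
}

#' Default stressor-response parameters
#'
#' Per-load run responses and the high-stress-work response used by
#' [sim_config()]. Post-event HR offsets are positive (elevation), post-event
#' HRV offsets are subtracted (suppression); both decay exponentially from the
#' event end. `during_frac_hrr` places during-run HR on the heart-rate-reserve
#' scale; high-stress work instead applies its (smaller) offsets during the
#' event itself.
#'
#' @return Nested list keyed by event type (and run load).
#' @export
default_response_params <- function() {
  list(
    run = list(
      light    = list(delta_hr_bpm = 0.5, delta_hrv_ms = 1,  tau_hr_min = 45,
                      tau_hrv_min = 60,  during_frac_hrr = 0.45, duration_min = 25),
      moderate = list(delta_hr_bpm = 6,   delta_hrv_ms = 10, tau_hr_min = 90,
                      tau_hrv_min = 150, during_frac_hrr = 0.65, duration_min = 45),
      vigorous = list(delta_hr_bpm = 9,   delta_hrv_ms = 16, tau_hr_min = 100,
                      tau_hrv_min = 180, during_frac_hrr = 0.85, duration_min = 75)),
    high_stress_work = list(delta_hr_bpm = 4, delta_hrv_ms = 8, tau_hr_min = 60,
                            tau_hrv_min = 120, duration_min = 115))
}

sw_config_error <- function(field, msg) {
  stop(sprintf("invalid simulation config: field '%s' %s", field, msg),
       call. = FALSE)
}

validate_sim_config <- function(cfg) {
  pos <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      sw_config_error(field, "must be a single strictly positive number")
  }
  for (f in c("n_users", "n_days", "accel_rate_hz", "hr_mesor_bpm",
              "hr_circ_amplitude_frac", "hrv_mesor_ms", "hrv_circ_amplitude_frac",
              "sleep_duration_h", "hr_max_bpm", "motion_threshold_g",
              "accel_rest_g", "accel_rest_noise_g"))
    pos(f)
  nonneg <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      sw_config_error(field, "must be a single non-negative number")
  }
  for (f in c("hr_between_user_sd_bpm", "hrv_between_user_sd_frac",
              "sleep_jitter_sd_h", "fidget_rate_per_h"))
    nonneg(f)
  if (cfg$hr_mesor_bpm < 30 || cfg$hr_mesor_bpm > 120)
    sw_config_error("hr_mesor_bpm", "must lie in [30, 120]")
  if (cfg$hrv_mesor_ms < 5 || cfg$hrv_mesor_ms > 200)
    sw_config_error("hrv_mesor_ms", "must lie in [5, 200]")
  if (cfg$missing_day_prob < 0 || cfg$missing_day_prob >= 1)
    sw_config_error("missing_day_prob", "must lie in [0, 1)")
  if (cfg$sleep_onset_hour < 0 || cfg$sleep_onset_hour >= 24)
    sw_config_error("sleep_onset_hour", "must lie in [0, 24)")
  ev <- cfg$events_per_user
  if (length(ev) && (is.null(names(ev)) ||
                     !all(names(ev) %in% c("run", "high_stress_work"))))
    sw_config_error("events_per_user",
                    "must be named counts for 'run'/'high_stress_work'")
  if (length(ev) && any(ev < 0))
    sw_config_error("events_per_user", "counts must be non-negative")
  if (sum(ev) > cfg$n_days)
    sw_config_error("events_per_user",
                    "at most one event per day: total events exceed n_days")
  mix <- cfg$run_load_mix
  if (!all(names(mix) %in% c("light", "moderate", "vigorous")) ||
      any(mix < 0) || sum(mix) <= 0)
    sw_config_error("run_load_mix", "must be non-negative weights over light/moderate/vigorous")
  if (!is.numeric(cfg$rng_seed) || length(cfg$rng_seed) != 1 || is.na(cfg$rng_seed))
    sw_config_error("rng_seed", "must be a single integer")
  invisible(cfg)
}

#' @export
print.sw_sim_config <- function(x, ...) {
  cat("Synthetic wearable cohort configuration\n")
  cat(sprintf("  users: %d, days: %d (missing-day prob %.2f)\n",
              x$n_users, x$n_days, x$missing_day_prob))
  cat(sprintf("  HR: mesor %.1f bpm, circadian amplitude %.1f%%\n",
              x$hr_mesor_bpm, 100 * x$hr_circ_amplitude_frac))
  cat(sprintf("  RMSSD: mesor %.1f ms, circadian amplitude %.1f%%\n",
              x$hrv_mesor_ms, 100 * x$hrv_circ_amplitude_frac))
  cat(sprintf("  sleep: onset %.1f h, duration %.1f h\n",
              x$sleep_onset_hour, x$sleep_duration_h))
  if (sum(x$events_per_user) > 0) {
    cat("  events/user:",
        paste(names(x$events_per_user), x$events_per_user,
              sep = "=", collapse = ", "), "\n")
  }
  cat(sprintf("  seed: %d\n", x$rng_seed))
  invisible(x)
}
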