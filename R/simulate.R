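#' @title Synthetic wearable cohort generator
#' @name simulate_cohort
#' @description
#' Generates per-user wearable streams (beat-to-beat RR intervals,
#' accelerometer magnitude, logged activity events, sleep schedule) with known
#' circadian structure and stressor-response kinetics, plus the ground truth
#' needed for parameter-recovery testing.
#'
#' @details
#' All randomness derives from the root seed `config$rng_seed` via a fixed
#' stream-splitting scheme: cohort-level draws (user profiles, sleep
#' schedules, missing days, event placement) use stream 0 and each user's RR
#' and accelerometer streams use streams 1 and 2 keyed by user index, so any
#' single stream can be regenerated independently. Identical config + seed
#' give an identical cohort.
#'
#' Whole days are dropped with probability `missing_day_prob` (no intra-day
#' gaps by default). Events are placed at most one per day, during waking
#' hours, on days that have data.
NULL

# seed splitting: exact in doubles for root < 2^31, result < 2^31
derive_seed <- function(root, user, stream) {
  as.integer(((as.double(root) %% 2147483647) * 1009 + user * 131 + stream) %%
               2147483647)
}

events_to_matrix <- function(events) {
  if (is.null(events) || nrow(events) == 0) {
    return(matrix(numeric(0), ncol = 8))
  }
  cbind(events$start_s, events$end_s,
        events$delta_hr_bpm, events$tau_hr_min * 60,
        events$delta_hrv_ms, events$tau_hrv_min * 60,
        events$during_delta_hr_bpm, events$during_delta_hrv_ms)
}

#' Simulate a beat-to-beat RR-interval stream
#'
#' Event-driven generator: beat *i* falls at `t[i-1] + rr[i]/1000` with
#' `rr = 60000 / HR(t) + eps`, where `HR(t)` is a single-harmonic circadian
#' sinusoid (plus any event-response offsets) and `eps` is white Gaussian
#' noise with SD `RMSSD_target(t) / sqrt(2)`, so the theoretical RMSSD of the
#' noise equals the circadian RMSSD target at that time.
#'
#' @param profile Named list: `hr_mesor_bpm`, `hr_amp_bpm`, `hr_peak_h`
#'   (clock hour of the HR maximum), `hrv_mesor_ms`, `hrv_amp_ms`,
#'   `hrv_peak_h`.
#' @param t0,t_end Span in seconds from the cohort epoch.
#' @param events Optional event-response table (as produced internally by
#'   [simulate_cohort()]) with columns `start_s`, `end_s`, `delta_hr_bpm`,
#'   `tau_hr_min`, `delta_hrv_ms`, `tau_hrv_min`, `during_delta_hr_bpm`,
#'   `during_delta_hrv_ms`.
#' @param noise Add beat-to-beat noise? A zero RMSSD target
#'   (`hrv_mesor_ms = 0`, allowed only for testing) forces a noiseless stream
#'   reproducing `60000/HR(t)` exactly.
#' @param seed Optional integer seed set before generation.
#' @return A `data.frame` (`sw_beats`) with `beat_time_s`, `rr_ms`; the
#'   generating profile, events and seed are kept as attributes so the stream
#'   can be re-derived (see [inject_event_response()]).
#' @export
simulate_rr_stream <- function(profile, t0, t_end, events = NULL,
                               noise = TRUE, seed = NULL) {
  stopifnot(t_end > t0)
  if (!is.null(seed)) set.seed(seed)
  if (profile$hrv_mesor_ms == 0 && profile$hrv_amp_ms == 0) noise <- FALSE
  ev <- events_to_matrix(events)
  res <- cpp_simulate_rr(t0, t_end,
                         profile$hr_mesor_bpm, profile$hr_amp_bpm,
                         profile$hr_peak_h,
                         profile$hrv_mesor_ms, profile$hrv_amp_ms,
                         profile$hrv_peak_h,
                         ev, noise)
  beats <- structure(list(beat_time_s = res$beat_time_s, rr_ms = res$rr_ms),
                     class = "data.frame",
                     row.names = c(NA, -length(res$rr_ms)))
  attr(beats, "profile") <- profile
  attr(beats, "events") <- events
  attr(beats, "span") <- c(t0, t_end)
  attr(beats, "seed") <- seed
  attr(beats, "noise") <- noise
  class(beats) <- c("sw_beats", "data.frame")
  beats
}

#' Add an event response to a simulated RR stream
#'
#' Injects post-event kinetics into an existing simulated stream: for
#' `t > end_s` the instantaneous HR gains `+delta_hr_bpm * exp(-(t-end)/tau)`
#' and the RMSSD target loses `delta_hrv_ms * exp(-(t-end)/tau)`, floored at
#' 1 ms. For `high_stress_work` the offsets also apply during the event. The
#' stream is re-derived from its stored generator state (same seed), so a
#' zero response returns the identical stream.
#'
#' @param beats A stream from [simulate_rr_stream()] carrying its generator
#'   attributes.
#' @param event List or one-row data.frame with `start_s`, `end_s`, `type`
#'   (`"run"` or `"high_stress_work"`).
#' @param response_params List with `delta_hr_bpm`, `delta_hrv_ms`,
#'   `tau_hr_min`, `tau_hrv_min`, and optionally `during_delta_hr_bpm`,
#'   `during_delta_hrv_ms` (defaults: the post deltas for high-stress work,
#'   0 for runs).
#' @return A new `sw_beats` stream; the injected event is recorded in its
#'   `events` attribute.
#' @export
inject_event_response <- function(beats, event, response_params) {
  stopifnot(inherits(beats, "sw_beats"))
  profile <- attr(beats, "profile")
  span <- attr(beats, "span")
  if (is.null(profile) || is.null(span))
    stop("beats do not carry generator attributes; cannot re-derive the stream")
  if (event$end_s > span[2] || event$start_s < span[1])
    stop("event lies outside the stream span")
  is_hsw <- !is.null(event$type) && event$type == "high_stress_work"
  p <- response_params
  new_row <- data.frame(
    start_s = event$start_s, end_s = event$end_s,
    delta_hr_bpm = p$delta_hr_bpm, tau_hr_min = p$tau_hr_min,
    delta_hrv_ms = p$delta_hrv_ms, tau_hrv_min = p$tau_hrv_min,
    during_delta_hr_bpm = if (!is.null(p$during_delta_hr_bpm))
      p$during_delta_hr_bpm else if (is_hsw) p$delta_hr_bpm else 0,
    during_delta_hrv_ms = if (!is.null(p$during_delta_hrv_ms))
      p$during_delta_hrv_ms else if (is_hsw) p$delta_hrv_ms else 0)
  events <- rbind(attr(beats, "events"), new_row)
  simulate_rr_stream(profile, span[1], span[2], events = events,
                     noise = attr(beats, "noise"), seed = attr(beats, "seed"))
}

#' Simulate an accelerometer-magnitude stream
#'
#' Low-noise around the rest level (1 g gravity) at rest, sustained
#' high-magnitude motion over the full span of every run, and short random
#' fidget bouts at a Poisson rate. High-stress work is treated as sedentary
#' (no forced motion), so motionless windows exist during those events.
#'
#' @param t0,t_end Span, seconds.
#' @param events Event table (`type`, `start_s`, `end_s`); only `type ==
#'   "run"` forces motion.
#' @param rate_hz Sampling rate.
#' @param fidget_rate_per_h Poisson rate of spontaneous motion bouts.
#' @param rest_g,rest_noise_g Rest level and its noise SD (g).
#' @param seed Optional integer seed.
#' @return A `data.frame` (`sw_motion`) with `sample_time_s`, `magnitude_g`.
#' @export
simulate_motion_stream <- function(t0, t_end, events = NULL, rate_hz = 1,
                                   fidget_rate_per_h = 2, rest_g = 1,
                                   rest_noise_g = 0.005, seed = NULL) {
  stopifnot(t_end > t0, rate_hz > 0)
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(t0, t_end - 1 / rate_hz, by = 1 / rate_hz)
  mag <- rest_g + rnorm(length(tt), 0, rest_noise_g)
  hours <- (t_end - t0) / 3600
  n_fidget <- rpois(1, fidget_rate_per_h * hours)
  n <- length(tt)
  # uniform sampling: [a, b) maps to an index slice directly
  slice <- function(a, b) {  # indices with a <= tt < b
    i1 <- max(ceiling((a - t0) * rate_hz) + 1, 1)
    i2 <- min(ceiling((b - t0) * rate_hz), n)
    if (i2 < i1) integer(0) else i1:i2
  }
  if (n_fidget > 0) {
    fs <- runif(n_fidget, t0, t_end)
    fd <- runif(n_fidget, 5, 30)
    fa <- runif(n_fidget, 0.1, 0.5)
    for (i in seq_len(n_fidget)) {
      idx <- slice(fs[i], fs[i] + fd[i])
      if (length(idx))
        mag[idx] <- mag[idx] + fa[i] * (0.5 + runif(length(idx), 0, 0.5))
    }
  }
  if (!is.null(events) && nrow(events) > 0) {
    runs <- events[events$type == "run", , drop = FALSE]
    for (i in seq_len(nrow(runs))) {
      idx <- slice(runs$start_s[i], runs$end_s[i] + 0.5 / rate_hz)
      mag[idx] <- rest_g + runif(length(idx), 0.3, 1.0)
    }
  }
  structure(list(sample_time_s = tt, magnitude_g = mag),
            class = c("sw_motion", "data.frame"),
            row.names = c(NA, -length(tt)))
}

# cohort-level draws: profiles, schedules, missing days, event placement
plan_cohort <- function(config) {
  cfg <- config
  set.seed(derive_seed(cfg$rng_seed, 0, 0))
  n <- cfg$n_users
  mid_sleep_h <- (cfg$sleep_onset_hour + cfg$sleep_duration_h / 2) %% 24
  wake_h <- (cfg$sleep_onset_hour + cfg$sleep_duration_h) %% 24

  hr_mesor <- pmin(pmax(cfg$hr_mesor_bpm +
                          rnorm(n, 0, cfg$hr_between_user_sd_bpm), 35), 115)
  hrv_mesor <- pmin(pmax(cfg$hrv_mesor_ms *
                           exp(rnorm(n, 0, cfg$hrv_between_user_sd_frac)), 5), 200)
  profiles <- data.frame(
    user_id = sprintf("user_%03d", seq_len(n)),
    hr_mesor_bpm = hr_mesor,
    hr_amp_bpm = cfg$hr_circ_amplitude_frac * hr_mesor,
    hr_peak_h = (mid_sleep_h + 12) %% 24,
    hrv_mesor_ms = hrv_mesor,
    hrv_amp_ms = cfg$hrv_circ_amplitude_frac * hrv_mesor,
    hrv_peak_h = (wake_h - 1) %% 24,
    stringsAsFactors = FALSE)

  sleeps <- vector("list", n)
  days_present <- vector("list", n)
  events <- vector("list", n)
  ev_counts <- cfg$events_per_user
  types <- rep(names(ev_counts), times = as.integer(ev_counts))
  next_event_id <- 1L
  for (u in seq_len(n)) {
    days <- 0:(cfg$n_days - 1)
    present <- days[runif(cfg$n_days) >= cfg$missing_day_prob]
    days_present[[u]] <- present
    onset_s <- days * 86400 +
      (cfg$sleep_onset_hour + rnorm(cfg$n_days, 0, cfg$sleep_jitter_sd_h)) * 3600
    sl <- data.frame(day = days, sleep_onset_s = onset_s,
                     wake_onset_s = onset_s + cfg$sleep_duration_h * 3600)
    sleeps[[u]] <- sl[sl$day %in% present, , drop = FALSE]

    if (length(types)) {
      ev_days <- sample(present, min(length(types), length(present)))
      rows <- vector("list", length(ev_days))
      for (k in seq_along(ev_days)) {
        type <- types[k]
        if (type == "run") {
          load <- sample(names(cfg$run_load_mix), 1, prob = cfg$run_load_mix)
          p <- cfg$response_params$run[[load]]
          during_hr <- p$during_frac_hrr * (cfg$hr_max_bpm - hr_mesor[u])
          during_hrv <- 0.8 * hrv_mesor[u]
        } else {
          load <- NA_character_
          p <- cfg$response_params$high_stress_work
          during_hr <- p$delta_hr_bpm
          during_hrv <- p$delta_hrv_ms
        }
        start_s <- ev_days[k] * 86400 + runif(1, wake_h + 2, wake_h + 8) * 3600
        rows[[k]] <- data.frame(
          event_id = sprintf("ev_%05d", next_event_id),
          user_id = profiles$user_id[u], type = type, load = load,
          start_s = start_s, end_s = start_s + p$duration_min * 60,
          delta_hr_bpm = p$delta_hr_bpm, tau_hr_min = p$tau_hr_min,
          delta_hrv_ms = p$delta_hrv_ms, tau_hrv_min = p$tau_hrv_min,
          during_delta_hr_bpm = during_hr, during_delta_hrv_ms = during_hrv,
          stringsAsFactors = FALSE)
        next_event_id <- next_event_id + 1L
      }
      events[u] <- list(do.call(rbind, rows))
    } else {
      events[u] <- list(NULL)
    }
  }
  list(profiles = profiles, sleeps = sleeps, days_present = days_present,
       events = events)
}

simulate_user_streams <- function(config, plan, u) {
  cfg <- config
  prof <- as.list(plan$profiles[u, ])
  t_end <- cfg$n_days * 86400
  ev <- plan$events[[u]]
  beats <- simulate_rr_stream(prof, 0, t_end, events = ev, noise = TRUE,
                              seed = derive_seed(cfg$rng_seed, u, 1))
  motion <- simulate_motion_stream(0, t_end, events = ev,
                                   rate_hz = cfg$accel_rate_hz,
                                   fidget_rate_per_h = cfg$fidget_rate_per_h,
                                   rest_g = cfg$accel_rest_g,
                                   rest_noise_g = cfg$accel_rest_noise_g,
                                   seed = derive_seed(cfg$rng_seed, u, 2))
  present <- plan$days_present[[u]]
  if (length(present) < cfg$n_days) {
    mask <- logical(cfg$n_days + 1)
    mask[present + 1L] <- TRUE
    ab <- attributes(beats)
    keep_b <- mask[floor(beats$beat_time_s / 86400) + 1L]  # mask has n_days+1 slots
    keep_m <- mask[floor(motion$sample_time_s / 86400) + 1L]
    bt <- beats$beat_time_s[keep_b]
    beats <- structure(list(beat_time_s = bt, rr_ms = beats$rr_ms[keep_b]),
                       class = c("sw_beats", "data.frame"),
                       row.names = c(NA, -length(bt)))
    for (a in setdiff(names(ab), c("names", "row.names", "class")))
      attr(beats, a) <- ab[[a]]
    mt <- motion$sample_time_s[keep_m]
    motion <- structure(list(sample_time_s = mt,
                             magnitude_g = motion$magnitude_g[keep_m]),
                        class = c("sw_motion", "data.frame"),
                        row.names = c(NA, -length(mt)))
  }
  list(beats = beats, motion = motion)
}

ground_truth_of_plan <- function(plan) {
  hours <- seq(0.5, 23.5, by = 1)
  hr_true <- vector("list", nrow(plan$profiles))
  for (u in seq_len(nrow(plan$profiles))) {
    p <- as.list(plan$profiles[u, ])
    tc <- cpp_true_curves(hours * 3600, p$hr_mesor_bpm, p$hr_amp_bpm,
                          p$hr_peak_h, p$hrv_mesor_ms, p$hrv_amp_ms,
                          p$hrv_peak_h, matrix(numeric(0), ncol = 8))
    hr_true[[u]] <- data.frame(user_id = p$user_id, hour_center = hours,
                               true_hr_bpm = tc$hr_bpm,
                               true_rmssd_ms = tc$rmssd_ms,
                               stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, plan$events)
  list(profiles = plan$profiles, hourly = do.call(rbind, hr_true),
       events = events)
}

#' Simulate a full synthetic cohort
#'
#' Runs the whole generator: user profiles, sleep schedules, whole-day
#' missingness, event placement, RR and accelerometer streams, and the
#' ground-truth record (one per simulated event) used for recovery tests.
#'
#' @param config A [sim_config()] object.
#' @return An `sw_cohort`: `users` (list per user of `user_id`, `beats`,
#'   `motion`, `events`, `sleep`), `ground_truth` (`profiles`, `hourly` true
#'   curves at hour centers, `events` with injected response parameters), and
#'   the `config`.
#' @seealso [simulate_cohort_windows()] for a memory-light variant that keeps
#'   only metric windows, [write_cohort()] for the on-disk layout.
#' @export
#' @examples
#' co <- simulate_cohort(sim_config(n_users = 1, n_days = 2,
#'                                  missing_day_prob = 0, rng_seed = 7))
#' head(co$users[[1]]$beats)
simulate_cohort <- function(config) {
  validate_sim_config(config)
  plan <- plan_cohort(config)
  users <- vector("list", config$n_users)
  for (u in seq_len(config$n_users)) {
    s <- simulate_user_streams(config, plan, u)
    users[[u]] <- list(user_id = plan$profiles$user_id[u],
                       beats = s$beats, motion = s$motion,
                       events = plan$events[[u]],
                       sleep = plan$sleeps[[u]])
  }
  out <- list(users = users, ground_truth = ground_truth_of_plan(plan),
              config = config)
  class(out) <- "sw_cohort"
  out
}

#' Simulate a cohort and keep only metric windows
#'
#' Streams users one at a time: simulates each user's RR and accelerometer
#' streams, computes motion-gated metric windows with
#' [compute_metric_windows()], and discards the raw streams. This keeps the
#' memory footprint of large cohorts (tens of users over 28 days) small.
#'
#' @param config A [sim_config()] object.
#' @param metric_params Optional list of overrides passed to
#'   [compute_metric_windows()] (`step_s`, `block_s`, `threshold_g`, ...).
#' @return List with `windows` (all users, with `user_id` column), `events`,
#'   `sleep` (with `user_id`), `ground_truth`, `config`.
#' @export
simulate_cohort_windows <- function(config, metric_params = list()) {
  validate_sim_config(config)
  plan <- plan_cohort(config)
  win <- vector("list", config$n_users)
  sleeps <- vector("list", config$n_users)
  for (u in seq_len(config$n_users)) {
    s <- simulate_user_streams(config, plan, u)
    args <- c(list(beats = s$beats, motion = s$motion,
                   events = plan$events[[u]],
                   rest_g = config$accel_rest_g,
                   threshold_g = config$motion_threshold_g),
              metric_params)
    w <- do.call(compute_metric_windows, args)
    w$user_id <- plan$profiles$user_id[u]
    win[[u]] <- w
    sl <- plan$sleeps[[u]]
    sl$user_id <- plan$profiles$user_id[u]
    sleeps[[u]] <- sl
    rm(s)
  }
  list(windows = as.data.frame(data.table::rbindlist(win)),
       events = do.call(rbind, plan$events),
       sleep = as.data.frame(data.table::rbindlist(sleeps)),
       ground_truth = ground_truth_of_plan(plan),
       config = config)
}

#' @export
print.sw_cohort <- function(x, ...) {
  nb <- vapply(x$users, function(u) nrow(u$beats), numeric(1))
  ne <- sum(vapply(x$users, function(u)
    if (is.null(u$events)) 0L else nrow(u$events), integer(1)))
  cat(sprintf("Synthetic wearable cohort: %d users, %d days, seed %d\n",
              x$config$n_users, x$config$n_days, x$config$rng_seed))
  cat(sprintf("  beats/user: %s (total %.1fM), events: %d\n",
              paste(range(nb), collapse = "-"), sum(nb) / 1e6, ne))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' One directory per user containing `rr.csv` (`timestamp_s, rr_ms`),
#' `accel.csv` (`timestamp_s, magnitude_g`), `events.csv`
#' (`event_id, type, start_s, end_s`), `sleep.csv`
#' (`sleep_onset_s, wake_onset_s`) and `ground_truth.json`. Timestamps are
#' seconds from the cohort epoch (UTC-like, no DST).
#'
#' @param cohort An `sw_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of user directories written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sw_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- cohort$ground_truth
  out <- character(length(cohort$users))
  for (i in seq_along(cohort$users)) {
    u <- cohort$users[[i]]
    ud <- file.path(dir, u$user_id)
    dir.create(ud, showWarnings = FALSE)
    data.table::fwrite(data.frame(timestamp_s = u$beats$beat_time_s,
                                  rr_ms = u$beats$rr_ms),
                       file.path(ud, "rr.csv"))
    data.table::fwrite(data.frame(timestamp_s = u$motion$sample_time_s,
                                  magnitude_g = u$motion$magnitude_g),
                       file.path(ud, "accel.csv"))
    ev <- u$events
    if (is.null(ev))
      ev <- data.frame(event_id = character(0), type = character(0),
                       start_s = numeric(0), end_s = numeric(0))
    data.table::fwrite(ev[, c("event_id", "type", "start_s", "end_s")],
                       file.path(ud, "events.csv"))
    data.table::fwrite(u$sleep[, c("sleep_onset_s", "wake_onset_s")],
                       file.path(ud, "sleep.csv"))
    gtu <- list(profile = as.list(gt$profiles[gt$profiles$user_id == u$user_id, ]),
                events = if (!is.null(gt$events))
                  gt$events[gt$events$user_id == u$user_id, ] else NULL)
    jsonlite::write_json(gtu, file.path(ud, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    out[i] <- ud
  }
  invisible(out)
}

#' Read one user's streams from a cohort directory
#'
#' @param user_dir Directory written by [write_cohort()].
#' @return List with `beats`, `motion`, `events`, `sleep`.
#' @export
read_user_dir <- function(user_dir) {
  rr <- data.table::fread(file.path(user_dir, "rr.csv"), data.table = FALSE)
  ac <- data.table::fread(file.path(user_dir, "accel.csv"), data.table = FALSE)
  ev <- data.table::fread(file.path(user_dir, "events.csv"), data.table = FALSE)
  sl <- data.table::fread(file.path(user_dir, "sleep.csv"), data.table = FALSE)
  list(beats = data.frame(beat_time_s = rr$timestamp_s, rr_ms = rr$rr_ms),
       motion = data.frame(sample_time_s = ac$timestamp_s,
                           magnitude_g = ac$magnitude_g),
       events = ev, sleep = sl)
}
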