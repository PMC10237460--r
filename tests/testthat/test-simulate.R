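test_that("config validation names the offending field", {
  expect_error(sim_config(n_users = 0), "n_users")
  expect_error(sim_config(missing_day_prob = 1), "missing_day_prob")
  expect_error(sim_config(hr_mesor_bpm = 150), "hr_mesor_bpm")
  expect_error(sim_config(hrv_mesor_ms = 2), "hrv_mesor_ms")
  expect_error(sim_config(n_days = 3, events_per_user = c(run = 5)),
               "events_per_user")
})

test_that("identical config and seed give an identical cohort", {
  cfg <- sim_config(n_users = 2, n_days = 3, events_per_user = c(run = 1),
                    rng_seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  # a different seed changes the streams
  c2 <- simulate_cohort(sim_config(n_users = 2, n_days = 3,
                                   events_per_user = c(run = 1), rng_seed = 8))
  expect_false(identical(a$users[[1]]$beats$rr_ms, c2$users[[1]]$beats$rr_ms))
})

test_that("zero missingness keeps every day; ground truth has one record per event", {
  cfg <- sim_config(n_users = 4, n_days = 6, missing_day_prob = 0,
                    events_per_user = c(run = 2), rng_seed = 3)
  co <- simulate_cohort(cfg)
  for (u in co$users) {
    days <- unique(floor(u$beats$beat_time_s / 86400))
    expect_setequal(days, 0:5)
  }
  gt <- co$ground_truth$events
  expect_equal(nrow(gt), 4 * 2)
  expect_equal(sum(gt$type == "run"), 8)
  expect_equal(anyDuplicated(gt$event_id), 0)
})

test_that("noiseless limits reproduce the analytic curves", {
  # constant HR 60, zero noise: all RR exactly 1000 ms
  b <- simulate_rr_stream(flat_profile(hr = 60, hrv = 0), 0, 1800)
  expect_equal(b$rr_ms, rep(1000, nrow(b)))
  expect_equal(diff(b$beat_time_s), rep(1, nrow(b) - 1))

  # sinusoidal HR, zero noise: windowed mean HR tracks the analytic curve
  p <- flat_profile(hr = 60, hrv = 0, hr_amp = 3)
  b <- simulate_rr_stream(p, 0, 86400)
  w <- compute_metric_windows(b, quiet_motion(0, 86400))
  truth <- 60 + 3 * cos(2 * pi * ((w$center_time_s / 3600) %% 24 - 15) / 24)
  expect_lt(max(abs(w$hr_motionless_bpm - truth)), 0.1)
})

test_that("white RR noise scaled by 1/sqrt(2) hits the RMSSD target", {
  # the sqrt(2) relation: successive differences of iid noise have
  # variance 2*sigma^2, so sigma = target/sqrt(2) gives RMSSD = target
  b <- simulate_rr_stream(flat_profile(hr = 60, hrv = 50), 0, 3e4, seed = 99)
  expect_gt(nrow(b), 1e4)
  expect_lt(abs(rmssd(b$rr_ms) - 50) / 50, 0.02)
})

test_that("RR streams are physical: positive intervals, increasing times", {
  cfg <- sim_config(n_users = 2, n_days = 2, events_per_user = c(run = 1),
                    missing_day_prob = 0, rng_seed = 21)
  co <- simulate_cohort(cfg)
  for (u in co$users) {
    expect_true(all(u$beats$rr_ms > 0))
    expect_true(all(diff(u$beats$beat_time_s) > 0))
    expect_true(all(u$motion$magnitude_g >= 0))
  }
})

test_that("HR profiles that leave the physiological range are rejected", {
  expect_error(simulate_rr_stream(flat_profile(hr = 60, hr_amp = 59), 0, 3600),
               "physiological|non-positive")
  b <- simulate_rr_stream(flat_profile(hr = 60, hrv = 0), 0, 7200)
  expect_error(
    inject_event_response(b, list(start_s = 100, end_s = 200, type = "run"),
                          list(delta_hr_bpm = 200, delta_hrv_ms = 0,
                               tau_hr_min = 60, tau_hrv_min = 60)),
    "physiological")
})

test_that("motion stream is quiet at rest, saturated during runs", {
  m <- simulate_motion_stream(0, 3600, fidget_rate_per_h = 0, seed = 5)
  expect_true(all(abs(m$magnitude_g - 1) < 0.05))
  ev <- data.frame(type = "run", start_s = 36000, end_s = 38400)
  m2 <- simulate_motion_stream(0, 86400, events = ev, fidget_rate_per_h = 0,
                               seed = 6)
  during <- m2$sample_time_s >= 36000 & m2$sample_time_s <= 38400
  expect_true(all(abs(m2$magnitude_g[during] - 1) > 0.05))
  expect_true(all(abs(m2$magnitude_g[!during] - 1) < 0.05))
})

test_that("fidget bouts arrive at the configured Poisson rate", {
  # brute-force count over seeds: mean count within 4 SE of lambda * hours
  lambda <- 3
  hours <- 12
  counts <- vapply(1:40, function(s) {
    m <- simulate_motion_stream(0, hours * 3600, fidget_rate_per_h = lambda,
                                rate_hz = 0.2, seed = 1000 + s)
    moving <- abs(m$magnitude_g - 1) > 0.05
    sum(diff(c(FALSE, moving)) == 1)  # rising edges ~ bouts
  }, numeric(1))
  mu <- lambda * hours
  se <- sqrt(mu / 40)
  expect_lt(abs(mean(counts) - mu), 4 * se + 1)
})

test_that("injected responses follow the exponential kinetics exactly", {
  p <- flat_profile(hr = 60, hrv = 0)
  b <- simulate_rr_stream(p, 0, 86400)
  ev <- list(start_s = 30000, end_s = 33000, type = "run")

  # null response leaves the stream untouched
  b0 <- inject_event_response(b, ev, list(delta_hr_bpm = 0, delta_hrv_ms = 0,
                                          tau_hr_min = 60, tau_hrv_min = 60))
  expect_equal(b0$rr_ms, b$rr_ms)

  # +6 bpm, tau 60 min: mean offset in (0, 30] min post-event equals the
  # closed-form bin average 6 * (tau/Delta) * (1 - exp(-Delta/tau))
  b1 <- inject_event_response(b, ev, list(delta_hr_bpm = 6, delta_hrv_ms = 0,
                                          tau_hr_min = 60, tau_hrv_min = 60))
  sel <- b1$beat_time_s > 33000 & b1$beat_time_s <= 33000 + 1800
  hr_inst <- 60000 / b1$rr_ms[sel]
  tau <- 3600
  expected <- 6 * (tau / 1800) * (1 - exp(-1800 / tau))
  expect_lt(abs(mean(hr_inst - 60) - expected), 0.02)

  # offset at t_end + 5 tau below 1% of delta
  t5 <- 33000 + 5 * 3600
  sel5 <- b1$beat_time_s > t5 & b1$beat_time_s < t5 + 600
  expect_lt(max(abs(60000 / b1$rr_ms[sel5] - 60)), 0.06)
})

test_that("cohort directories round-trip through the documented CSV layout", {
  cfg <- sim_config(n_users = 2, n_days = 2, events_per_user = c(run = 1),
                    missing_day_prob = 0, accel_rate_hz = 0.2, rng_seed = 13)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_length(paths, 2)
  expect_true(all(file.exists(file.path(paths, "rr.csv"))))
  back <- read_user_dir(paths[1])
  expect_equal(back$beats$rr_ms, co$users[[1]]$beats$rr_ms, tolerance = 1e-9)
  expect_equal(back$events$event_id, co$users[[1]]$events$event_id)
  gt <- jsonlite::read_json(file.path(paths[1], "ground_truth.json"))
  expect_equal(gt$profile$user_id, co$users[[1]]$user_id)
})
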