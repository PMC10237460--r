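# constant-baseline fixture shared across impact tests
impact_fixture <- function(hr = 60, hrv = 50) {
  w <- windows_frame("u1", seq(0, 28 * 86400 - 300, by = 300), hr, hrv)
  list(windows = w, baseline = hourly_medians(w))
}

test_that("run load classification follows the HRR zone score", {
  # entire run below 50% HRR: weight 0 everywhere -> light
  light <- classify_run_load(rep(120, 30), hr_max_bpm = 190, hr_rest_bpm = 60)
  expect_equal(as.character(light), "light")
  expect_equal(attr(light, "score"), 0)
  # 45 min at 65% HRR: weight 2 -> score 90 -> moderate
  hr65 <- 60 + 0.65 * 130
  mod <- classify_run_load(rep(hr65, 45), 190, 60)
  expect_equal(as.character(mod), "moderate")
  expect_equal(attr(mod, "score"), 90)
  # 60 min at 85% HRR: weight 4 -> score 240 -> vigorous
  hr85 <- 60 + 0.85 * 130
  vig <- classify_run_load(rep(hr85, 60), 190, 60)
  expect_equal(as.character(vig), "vigorous")
  expect_equal(attr(vig, "score"), 240)
  expect_error(classify_run_load(numeric(0), 190, 60), "unclassifiable")
  expect_error(classify_run_load(rep(100, 10), 60, 60), "exceed")
})

test_that("a stream exactly at baseline yields all-zero deviation bins", {
  fx <- impact_fixture()
  ev <- list(event_id = "e1", user_id = "u1", type = "run",
             start_s = 10 * 86400 + 10 * 3600, end_s = 10 * 86400 + 11 * 3600)
  b <- bin_event_deviation(fx$windows, ev, fx$baseline)
  expect_equal(b$bin_label, c("Pre", sprintf("%d-%d", seq(0, 270, 30), seq(30, 300, 30))))
  expect_equal(b$delta_hr_bpm, rep(0, 11))
  expect_equal(b$delta_hrv_ms, rep(0, 11))
  # high-stress work additionally carries a During bin
  ev$type <- "high_stress_work"
  bh <- bin_event_deviation(fx$windows, ev, fx$baseline)
  expect_true("During" %in% bh$bin_label)
  expect_equal(nrow(bh), 12)
})

test_that("an injected 60-min step appears in the first two bins only", {
  fx <- impact_fixture()
  t_end <- 10 * 86400 + 11 * 3600
  w <- fx$windows
  step <- w$center_time_s >= t_end & w$center_time_s < t_end + 3600
  w$hr_motionless_bpm[step] <- 66
  ev <- list(event_id = "e1", user_id = "u1", type = "run",
             start_s = t_end - 3600, end_s = t_end)
  b <- bin_event_deviation(w, ev, fx$baseline)
  expect_equal(b$delta_hr_bpm[b$bin_label == "0-30"], 6)
  expect_equal(b$delta_hr_bpm[b$bin_label == "30-60"], 6)
  expect_equal(b$delta_hr_bpm[b$bin_label == "60-90"], 0)
  expect_equal(b$delta_hr_bpm[b$bin_label == "Pre"], 0)
})

test_that("time-of-day normalization uses the clock hour of the bin center", {
  # baseline hour 14 sits 4 bpm above the rest; an event whose 0-30 bin has
  # its center in hour 14 must be normalized against that hour's median
  w <- windows_frame("u1", seq(0, 28 * 86400 - 300, by = 300), 60, 50)
  h14 <- floor((w$center_time_s %% 86400) / 3600) == 14
  w$hr_motionless_bpm[h14] <- 64
  bl <- hourly_medians(w)
  t_end <- 5 * 86400 + 13 * 3600 + 2700  # 13:45; 0-30 bin center at 14:00
  ev <- list(event_id = "e1", user_id = "u1", type = "run",
             start_s = t_end - 1800, end_s = t_end)
  b <- bin_event_deviation(w, ev, bl)
  # hand oracle with the center-hour convention:
  #   bin mean = mean of window values in [t_end, t_end+30min): half are 60
  #   (13:45-14:00) and half 64 (14:00-14:15); hourly median of hour 14 is 64;
  #   Pre (13:15-13:45, hour 13) normalizes to 0
  raw <- mean(w$hr_motionless_bpm[w$center_time_s >= t_end &
                                    w$center_time_s < t_end + 1800])
  expect_equal(b$delta_hr_bpm[b$bin_label == "0-30"], raw - 64)
})

test_that("events without valid pre-event windows are excluded with a reason", {
  fx <- impact_fixture()
  w <- fx$windows
  pre <- w$center_time_s >= 10 * 86400 - 1800 & w$center_time_s < 10 * 86400
  w$valid[pre] <- FALSE
  ev <- list(event_id = "e9", user_id = "u1", type = "run",
             start_s = 10 * 86400, end_s = 10 * 86400 + 1800)
  expect_message(b <- bin_event_deviation(w, ev, fx$baseline), "no valid pre")
  expect_null(b)
})

test_that("bins with no valid windows are missing, not zero", {
  fx <- impact_fixture()
  t_end <- 10 * 86400 + 11 * 3600
  w <- fx$windows
  gap <- w$center_time_s >= t_end + 3600 & w$center_time_s < t_end + 5400
  w$valid[gap] <- FALSE
  ev <- list(event_id = "e1", user_id = "u1", type = "run",
             start_s = t_end - 3600, end_s = t_end)
  b <- bin_event_deviation(w, ev, fx$baseline)
  expect_true(is.na(b$delta_hr_bpm[b$bin_label == "60-90"]))
  expect_equal(b$n_windows[b$bin_label == "60-90"], 0)
})

test_that("double normalization annihilates a user-constant offset (frozen baseline)", {
  fx <- impact_fixture()
  ev <- list(event_id = "e1", user_id = "u1", type = "run",
             start_s = 8 * 86400 + 9 * 3600, end_s = 8 * 86400 + 10 * 3600)
  b0 <- bin_event_deviation(fx$windows, ev, fx$baseline)
  w_shift <- fx$windows
  w_shift$hr_motionless_bpm <- w_shift$hr_motionless_bpm + 7.5
  b1 <- bin_event_deviation(w_shift, ev, fx$baseline)  # baseline frozen
  expect_equal(b1$delta_hr_bpm, b0$delta_hr_bpm)
})

test_that("overlap exclusion drops contaminated events only when asked", {
  fx <- impact_fixture()
  d <- 6 * 86400
  events <- data.frame(
    event_id = c("a", "b"), user_id = "u1", type = "run",
    start_s = c(d + 9 * 3600, d + 11 * 3600),
    end_s = c(d + 10 * 3600, d + 11.5 * 3600), stringsAsFactors = FALSE)
  t1 <- event_deviation_table(fx$windows, events, fx$baseline)
  # b starts inside a's 5-hour post window, so a is contaminated; a ends
  # before b's pre window opens, so b survives
  expect_equal(attr(t1, "excluded")$event_id, "a")
  expect_setequal(unique(t1$event_id), "b")
  t2 <- event_deviation_table(fx$windows, events, fx$baseline,
                              exclude_overlaps = FALSE)
  expect_setequal(unique(t2$event_id), c("a", "b"))
})

make_bins <- function(event_id, values, centers_min = seq(15, by = 30,
                                                          length.out = length(values))) {
  data.frame(event_id = event_id,
             bin_label = sprintf("%d-%d", centers_min - 15, centers_min + 15),
             bin_center_s = centers_min * 60,
             delta_hr_bpm = values, delta_hrv_ms = values,
             n_windows = 10L, stringsAsFactors = FALSE)
}

test_that("trapezoidal AUC matches hand-computed areas", {
  expect_equal(event_auc(make_bins("z", rep(0, 10)))$auc_hr, 0)
  expect_equal(event_auc(make_bins("r", c(2, 2)))$auc_hr, 60)
  expect_equal(event_auc(make_bins("t", c(4, 2, 0)))$auc_hr, 120)
  # linearity: scaling deviations scales the area
  b <- make_bins("l", c(3, 1, 4, 1, 5))
  b5 <- b
  b5$delta_hr_bpm <- 5 * b5$delta_hr_bpm
  expect_equal(event_auc(b5)$auc_hr, 5 * event_auc(b)$auc_hr)
  # missing interior bins are bridged linearly
  bm <- make_bins("m", c(4, NA, 0))
  expect_equal(event_auc(bm)$auc_hr, (4 + 0) / 2 * 60)
  # fewer than 2 bins: excluded
  expect_message(a1 <- event_auc(make_bins("s", c(4, NA, NA))), "fewer than 2")
  expect_null(a1)
})
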