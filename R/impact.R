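post_bin_labels <- function(n_bins = 10) {
  sprintf("%d-%d", 30 * (seq_len(n_bins) - 1), 30 * seq_len(n_bins))
}

#' Classify a run's load from a heart-rate-reserve score
#'
#' Transparent surrogate for proprietary run scoring: each HR sample is
#' placed on the heart-rate-reserve (HRR) scale,
#' `%HRR = (hr - hr_rest) / (hr_max - hr_rest)`, weighted by zone
#' (`<0.5: 0`, `0.5-0.6: 1`, `0.6-0.7: 2`, `0.7-0.8: 3`, `0.8-0.9: 4`,
#' `>=0.9: 5`) and the score is the time-weighted sum `sum(w * minutes)`.
#' Scores below `thresholds[1]` are light, above `thresholds[2]` vigorous,
#' otherwise moderate. The cut-offs make no claim to reproduce any
#' commercial algorithm.
#'
#' @param run_hr_samples During-run HR samples, bpm (motion-contaminated HR
#'   is fine here; only the run itself is scored).
#' @param hr_max_bpm,hr_rest_bpm The user's maximal and resting HR.
#' @param sample_interval_min Minutes represented by each sample (default 1).
#' @param thresholds Length-2 score cut-offs (light/moderate, moderate/vigorous).
#' @return `"light"`, `"moderate"` or `"vigorous"`, with the numeric score as
#'   attribute `score`.
#' @export
#' @examples
#' classify_run_load(rep(155, 45), hr_max_bpm = 190, hr_rest_bpm = 60)
classify_run_load <- function(run_hr_samples, hr_max_bpm, hr_rest_bpm,
                              sample_interval_min = 1,
                              thresholds = c(60, 180)) {
  if (hr_max_bpm <= hr_rest_bpm) stop("hr_max_bpm must exceed hr_rest_bpm")
  if (length(run_hr_samples) == 0)
    stop("unclassifiable run: no HR samples")
  frac <- (run_hr_samples - hr_rest_bpm) / (hr_max_bpm - hr_rest_bpm)
  w <- findInterval(frac, c(0.5, 0.6, 0.7, 0.8, 0.9))
  score <- sum(w) * sample_interval_min
  load <- if (score < thresholds[1]) "light"
          else if (score > thresholds[2]) "vigorous"
          else "moderate"
  attr(load, "score") <- score
  load
}

#' Per-minute heart rate during an event
#'
#' Mean HR ([mean_hr()]) of the beats falling in each whole minute of
#' `[start_s, end_s)`; minutes without beats are dropped.
#'
#' @param beats Data frame with `beat_time_s`, `rr_ms`.
#' @param event List/row with `start_s`, `end_s`.
#' @return Numeric vector of per-minute HR, bpm.
#' @export
run_hr_minutes <- function(beats, event) {
  sel <- beats$beat_time_s >= event$start_s & beats$beat_time_s < event$end_s
  if (!any(sel)) return(numeric(0))
  b <- beats[sel, ]
  minute <- floor((b$beat_time_s - event$start_s) / 60)
  as.numeric(tapply(b$rr_ms, minute, function(rr) 60000 / mean(rr)))
}

#' Assign loads to a cohort's runs from simulated streams
#'
#' Applies [classify_run_load()] to every run in a simulated cohort, using
#' the user's daily median motionless HR as the resting HR.
#'
#' @param cohort An `sw_cohort` (streams retained).
#' @param baseline An [hourly_medians()] result (supplies resting HR).
#' @param hr_max_bpm Maximal HR assumed for all users.
#' @param ... Passed to [classify_run_load()].
#' @return The cohort's event table with a `load_classified` column
#'   (`NA` for non-runs or unclassifiable runs).
#' @export
classify_cohort_runs <- function(cohort, baseline, hr_max_bpm = 190, ...) {
  stopifnot(inherits(cohort, "sw_cohort"))
  daily <- attr(baseline, "daily")
  out <- vector("list", length(cohort$users))
  for (u in cohort$users) {
    ev <- u$events
    if (is.null(ev) || nrow(ev) == 0) next
    rest <- daily$daily_median_hr_bpm[daily$user_id == u$user_id]
    ev$load_classified <- NA_character_
    for (i in seq_len(nrow(ev))) {
      if (ev$type[i] != "run" || length(rest) == 0) next
      hr <- run_hr_minutes(u$beats, ev[i, ])
      if (length(hr) == 0) next
      ev$load_classified[i] <- classify_run_load(hr, hr_max_bpm, rest, ...)
    }
    out[[length(out) + 1]] <- ev
  }
  do.call(rbind, out)
}

bin_grid_for_event <- function(event, n_post_bins = 10) {
  is_hsw <- !is.null(event$type) && !is.na(event$type) &&
    event$type == "high_stress_work"
  g <- data.frame(
    bin_label = "Pre",
    lo = event$start_s - 1800, hi = event$start_s,
    center_s = event$start_s - 900, stringsAsFactors = FALSE)
  if (is_hsw)
    g <- rbind(g, data.frame(bin_label = "During", lo = event$start_s,
                             hi = event$end_s,
                             center_s = (event$start_s + event$end_s) / 2))
  k <- seq_len(n_post_bins) - 1
  g <- rbind(g, data.frame(bin_label = post_bin_labels(n_post_bins),
                           lo = event$end_s + 1800 * k,
                           hi = event$end_s + 1800 * (k + 1),
                           center_s = event$end_s + 1800 * k + 900))
  g
}

#' Double-normalized 30-minute deviation bins around one event
#'
#' Aggregates valid metric windows into the pre-event bin (30 min before the
#' start), a During bin (high-stress work only; runs yield no motionless
#' windows), and ten 30-minute bins covering the 5 hours after the event end.
#' Each bin mean is first normalized to time of day by subtracting the user's
#' hourly median for the clock hour containing the bin center, then the Pre
#' value is subtracted, so each bin measures the event-attributable deviation
#' (`post - pre`: elevated post-event HR is positive) and Pre is 0 by
#' construction. Bins with no valid windows are `NA`, not zero.
#'
#' @param windows The user's `sw_windows` frame (a `user_id` column is
#'   allowed and checked against the event's).
#' @param event Row/list with `event_id`, `user_id`, `type`, `start_s`,
#'   `end_s`.
#' @param baseline An [hourly_medians()] result containing the user.
#' @param n_post_bins Number of 30-min post-event bins (default 10 = 300 min).
#' @return Data frame (`event_id`, `bin_label`, `bin_center_s`,
#'   `delta_hr_bpm`, `delta_hrv_ms`, `n_windows`), or `NULL` (with a message)
#'   if the event has no valid Pre windows or no baseline.
#' @export
bin_event_deviation <- function(windows, event, baseline, n_post_bins = 10) {
  uid <- event$user_id
  base_u <- baseline[baseline$user_id == uid, ]
  if (nrow(base_u) == 0) {
    message(sprintf("event %s excluded: user %s has no baseline",
                    event$event_id, uid))
    return(NULL)
  }
  w <- windows
  if ("user_id" %in% names(w)) w <- w[w$user_id == uid, ]
  w <- w[w$valid, ]
  g <- bin_grid_for_event(event, n_post_bins)

  norm_hr <- norm_hrv <- n_win <- numeric(nrow(g))
  for (i in seq_len(nrow(g))) {
    inb <- w$center_time_s >= g$lo[i] & w$center_time_s < g$hi[i]
    n_win[i] <- sum(inb)
    hour <- floor((g$center_s[i] %% 86400) / 3600)
    med_hr <- base_u$median_hr_bpm[base_u$hour_of_day == hour]
    med_hrv <- base_u$median_hrv_ms[base_u$hour_of_day == hour]
    if (n_win[i] == 0 || length(med_hr) == 0 || is.na(med_hr)) {
      norm_hr[i] <- NA_real_
      norm_hrv[i] <- NA_real_
    } else {
      norm_hr[i] <- mean(w$hr_motionless_bpm[inb]) - med_hr
      norm_hrv[i] <- mean(w$rmssd_ms[inb]) - med_hrv
    }
  }
  pre <- which(g$bin_label == "Pre")
  if (n_win[pre] == 0 || is.na(norm_hr[pre])) {
    message(sprintf("event %s excluded: no valid pre-event windows",
                    event$event_id))
    return(NULL)
  }
  data.frame(event_id = event$event_id, bin_label = g$bin_label,
             bin_center_s = g$center_s,
             delta_hr_bpm = norm_hr - norm_hr[pre],
             delta_hrv_ms = norm_hrv - norm_hrv[pre],
             n_windows = n_win, stringsAsFactors = FALSE)
}

#' Deviation bins for every event in a cohort
#'
#' Runs [bin_event_deviation()] over an event table, optionally excluding
#' events whose analysis span (30 min before the start to the end of the last
#' post bin) overlaps another logged event of the same user.
#'
#' @param windows All users' windows (`user_id` column required).
#' @param events Event table (`event_id`, `user_id`, `type`, `start_s`,
#'   `end_s`, optional `load`).
#' @param baseline An [hourly_medians()] result.
#' @param exclude_overlaps Drop events contaminated by another event
#'   (default TRUE).
#' @param n_post_bins Passed to [bin_event_deviation()].
#' @return `sw_bins` data frame with `user_id`, `type`, `load` carried
#'   through; excluded events are recorded in attribute `excluded`.
#' @export
event_deviation_table <- function(windows, events, baseline,
                                  exclude_overlaps = TRUE, n_post_bins = 10) {
  if (is.null(events) || nrow(events) == 0)
    stop("no events to analyse")
  excluded <- list()
  pieces <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (exclude_overlaps) {
      others <- events[events$user_id == ev$user_id &
                         events$event_id != ev$event_id, , drop = FALSE]
      span_lo <- ev$start_s - 1800
      span_hi <- ev$end_s + 1800 * n_post_bins
      if (nrow(others) > 0 &&
          any(others$end_s > span_lo & others$start_s < span_hi)) {
        excluded[[length(excluded) + 1]] <-
          data.frame(event_id = ev$event_id, reason = "overlapping event")
        next
      }
    }
    b <- bin_event_deviation(windows, ev, baseline, n_post_bins)
    if (is.null(b)) {
      excluded[[length(excluded) + 1]] <-
        data.frame(event_id = ev$event_id,
                   reason = "no baseline or no valid pre-event windows")
      next
    }
    b$user_id <- ev$user_id
    b$type <- ev$type
    b$load <- if ("load" %in% names(ev)) ev$load else NA_character_
    pieces[[length(pieces) + 1]] <- b
  }
  out <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(event_id = character(0), bin_label = character(0),
               bin_center_s = numeric(0), delta_hr_bpm = numeric(0),
               delta_hrv_ms = numeric(0), n_windows = integer(0),
               user_id = character(0), type = character(0),
               load = character(0))
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(event_id = character(0), reason = character(0))
  class(out) <- c("sw_bins", "data.frame")
  out
}

#' Trapezoidal area under one event's deviation curve
#'
#' Integrates the post-event deviation bins over their centers (15, 45, ...,
#' 285 min from the event end) with the trapezoidal rule, treating 0 as the
#' baseline. Missing interior bins are bridged linearly (the trapezoid simply
#' spans the surviving points). Pre and During bins are not part of the
#' curve.
#'
#' @param binned One event's bins from [bin_event_deviation()].
#' @return List with `event_id`, `auc_hr` (bpm*min), `auc_hrv` (ms*min), or
#'   `NULL` if fewer than 2 non-missing post-event bins exist.
#' @export
event_auc <- function(binned) {
  post <- binned[!binned$bin_label %in% c("Pre", "During"), ]
  centers_min <- (post$bin_center_s - post$bin_center_s[1]) / 60 + 15
  keep_hr <- !is.na(post$delta_hr_bpm)
  keep_hrv <- !is.na(post$delta_hrv_ms)
  if (sum(keep_hr) < 2 || sum(keep_hrv) < 2) {
    message(sprintf("event %s excluded from AUC: fewer than 2 post bins",
                    binned$event_id[1]))
    return(NULL)
  }
  list(event_id = binned$event_id[1],
       auc_hr = pracma::trapz(centers_min[keep_hr], post$delta_hr_bpm[keep_hr]),
       auc_hrv = pracma::trapz(centers_min[keep_hrv], post$delta_hrv_ms[keep_hrv]))
}

#' AUC for every event in a deviation-bin table
#'
#' @param bins An [event_deviation_table()] result.
#' @return Data frame: `event_id`, `user_id`, `type`, `load`, `auc_hr`,
#'   `auc_hrv`.
#' @export
auc_table <- function(bins) {
  ids <- unique(bins$event_id)
  rows <- list()
  for (id in ids) {
    b <- bins[bins$event_id == id, ]
    a <- event_auc(b)
    if (is.null(a)) next
    rows[[length(rows) + 1]] <-
      data.frame(event_id = id, user_id = b$user_id[1], type = b$type[1],
                 load = b$load[1], auc_hr = a$auc_hr, auc_hrv = a$auc_hrv,
                 stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event_id = character(0), user_id = character(0),
               type = character(0), load = character(0),
               auc_hr = numeric(0), auc_hrv = numeric(0))
  rownames(out) <- NULL
  out
}
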