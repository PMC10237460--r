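#' Per-user hourly-median circadian baseline
#'
#' For each user passing the inclusion rule (at least `min_days` distinct
#' data days within the first `span_days`-day span), computes the median of
#' valid-window motionless HR and RMSSD for each hour of the day, pooled over
#' the span, plus the user's daily medians over all valid windows. Hours with
#' fewer than `min_windows_per_hour` valid windows are kept as rows but
#' flagged missing (`NA` medians) rather than yielding an unstable median.
#'
#' @param windows `sw_windows`-style data frame with a `user_id` column.
#' @param span_days Analysis span in days from the cohort epoch; windows
#'   beyond it are ignored (at most 28 days of data are used).
#' @param min_days Inclusion threshold: distinct days with at least one valid
#'   window (default 25 of 28).
#' @param min_windows_per_hour Minimum valid windows for an hourly median.
#' @return `sw_baseline` data frame (`user_id`, `hour_of_day`,
#'   `median_hr_bpm`, `median_hrv_ms`, `n_windows`) with attributes `daily`
#'   (per-user daily medians, day counts) and `excluded` (users failing
#'   inclusion, with the reason).
#' @export
hourly_medians <- function(windows, span_days = 28, min_days = 25,
                           min_windows_per_hour = 3) {
  stopifnot("user_id" %in% names(windows))
  dt <- data.table::as.data.table(windows)
  dt <- dt[dt$valid & dt$center_time_s >= 0 &
             dt$center_time_s < span_days * 86400, ]
  dt[, `:=`(day = floor(center_time_s / 86400),
            hour = floor((center_time_s %% 86400) / 3600))]

  day_counts <- dt[, list(n_days = data.table::uniqueN(day)), by = "user_id"]
  all_users <- unique(windows$user_id)
  missing_users <- setdiff(all_users, day_counts$user_id)
  failing <- day_counts$user_id[day_counts$n_days < min_days]
  excluded <- data.frame(
    user_id = c(missing_users, failing),
    reason = c(rep("no valid windows in span", length(missing_users)),
               sprintf("only %d data days in %d-day span (need >= %d)",
                       day_counts$n_days[day_counts$n_days < min_days],
                       span_days, min_days)),
    stringsAsFactors = FALSE)
  if (nrow(excluded) > 0)
    message(sprintf("hourly_medians: excluded %d user(s) failing inclusion",
                    nrow(excluded)))
  dt <- dt[!dt$user_id %in% excluded$user_id, ]

  hourly <- dt[, list(median_hr_bpm = stats::median(hr_motionless_bpm),
                      median_hrv_ms = stats::median(rmssd_ms),
                      n_windows = .N),
               by = c("user_id", "hour")]
  # complete 24-hour grid; flag sparse hours as missing
  grid <- data.table::CJ(user_id = unique(dt$user_id), hour = 0:23)
  hourly <- hourly[grid, on = c("user_id", "hour")]
  hourly[is.na(n_windows), n_windows := 0L]
  hourly[n_windows < min_windows_per_hour,
         `:=`(median_hr_bpm = NA_real_, median_hrv_ms = NA_real_)]

  daily <- dt[, list(daily_median_hr_bpm = stats::median(hr_motionless_bpm),
                     daily_median_hrv_ms = stats::median(rmssd_ms),
                     n_days = data.table::uniqueN(day),
                     n_windows = .N),
              by = "user_id"]

  out <- as.data.frame(hourly[order(user_id, hour)])
  names(out)[names(out) == "hour"] <- "hour_of_day"
  attr(out, "daily") <- as.data.frame(daily)
  attr(out, "excluded") <- excluded
  attr(out, "params") <- list(span_days = span_days, min_days = min_days,
                              min_windows_per_hour = min_windows_per_hour)
  class(out) <- c("sw_baseline", "data.frame")
  out
}

rfd_ratio <- function(hourly, daily, mode) {
  switch(mode,
         hourly_over_daily = hourly / daily,
         daily_over_hourly = daily / hourly,
         stop("unknown rfd mode: ", mode))
}

#' Relative fractional difference by clock hour
#'
#' Expresses each hour's median relative to the user's daily median. The
#' default `hourly_over_daily` formulation puts a daily-typical hour at 1
#' with the plotted rhythm upright (an hour with HR 10 percent above the daily
#' median reads 1.10); `daily_over_hourly` is the inverted alternative
#' reading. A zero daily median leaves the hour flagged `NA`.
#'
#' @param baseline An [hourly_medians()] result.
#' @param mode `"hourly_over_daily"` (default) or `"daily_over_hourly"`.
#' @return `sw_rfd` data frame: `user_id`, `axis = "clock_hour"`,
#'   `bin_center_h` (0.5 ... 23.5), `rfd_hr`, `rfd_hrv`, `n_windows`.
#' @export
relative_fractional_difference <- function(baseline,
                                           mode = c("hourly_over_daily",
                                                    "daily_over_hourly")) {
  mode <- match.arg(mode)
  stopifnot(inherits(baseline, "sw_baseline"))
  daily <- attr(baseline, "daily")
  m <- merge(as.data.frame(baseline), daily[, c("user_id",
                                                "daily_median_hr_bpm",
                                                "daily_median_hrv_ms")],
             by = "user_id")
  zero <- m$daily_median_hr_bpm == 0 | m$daily_median_hrv_ms == 0
  out <- data.frame(
    user_id = m$user_id, axis = "clock_hour",
    bin_center_h = m$hour_of_day + 0.5,
    rfd_hr = ifelse(zero, NA_real_,
                    rfd_ratio(m$median_hr_bpm, m$daily_median_hr_bpm, mode)),
    rfd_hrv = ifelse(zero, NA_real_,
                     rfd_ratio(m$median_hrv_ms, m$daily_median_hrv_ms, mode)),
    n_windows = m$n_windows,
    stringsAsFactors = FALSE)
  out <- out[order(out$user_id, out$bin_center_h), ]
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  class(out) <- c("sw_rfd", "data.frame")
  out
}

#' Sleep- and wake-aligned circadian profiles
#'
#' Assigns each valid window a signed hour offset from the nearest sleep
#' (resp. wake) onset, bins offsets into 1-hour half-open bins `[k, k+1)`
#' with half-hour centers — covering -14.5 ... 8.5 h around sleep onset and
#' -8.5 ... 14.5 h around wake onset — takes per-user medians per bin, and
#' expresses them relative to the user's daily median with the configured
#' relative-fractional-difference formulation. A window exactly at onset
#' lands in bin +0.5. Days without a sleep record contribute no windows
#' (their offsets fall outside the bin ranges of the surrounding onsets).
#'
#' @param windows `sw_windows`-style frame with `user_id`.
#' @param sleep Sleep schedule with `user_id`, `sleep_onset_s`,
#'   `wake_onset_s`.
#' @param baseline An [hourly_medians()] result (supplies daily medians and
#'   the included-user set).
#' @param mode RFD formulation, see [relative_fractional_difference()].
#' @param min_windows Minimum valid windows per user-bin.
#' @return `sw_rfd` data frame with `axis` in `hours_from_sleep_onset`,
#'   `hours_from_wake_onset`.
#' @export
align_to_sleep_wake <- function(windows, sleep, baseline,
                                mode = c("hourly_over_daily",
                                         "daily_over_hourly"),
                                min_windows = 3) {
  mode <- match.arg(mode)
  stopifnot(inherits(baseline, "sw_baseline"))
  daily <- attr(baseline, "daily")
  span_days <- attr(baseline, "params")$span_days
  dt <- data.table::as.data.table(windows)
  dt <- dt[dt$valid & dt$user_id %in% daily$user_id &
             dt$center_time_s >= 0 & dt$center_time_s < span_days * 86400, ]

  align_axis <- function(onset_col, lo, hi, axis_name) {
    pieces <- vector("list", 0L)
    for (uid in unique(dt$user_id)) {
      onsets <- sort(sleep[[onset_col]][sleep$user_id == uid])
      if (length(onsets) == 0) next
      w <- dt[dt$user_id == uid, ]
      k <- findInterval(w$center_time_s, onsets)
      prev_off <- ifelse(k >= 1, (w$center_time_s - onsets[pmax(k, 1)]) / 3600, Inf)
      next_off <- ifelse(k < length(onsets),
                         (w$center_time_s - onsets[pmin(k + 1, length(onsets))]) / 3600,
                         -Inf)
      off <- ifelse(abs(prev_off) <= abs(next_off), prev_off, next_off)
      keep <- off >= lo & off < hi
      if (!any(keep)) next
      pieces[[length(pieces) + 1L]] <-
        data.frame(user_id = uid, bin = floor(off[keep]) + 0.5,
                   hr = w$hr_motionless_bpm[keep], hrv = w$rmssd_ms[keep],
                   stringsAsFactors = FALSE)
    }
    if (length(pieces) == 0) return(NULL)
    bd <- data.table::as.data.table(do.call(rbind, pieces))
    agg <- bd[, list(median_hr = stats::median(hr),
                     median_hrv = stats::median(hrv), n_windows = .N),
              by = c("user_id", "bin")]
    agg <- agg[agg$n_windows >= min_windows, ]
    m <- merge(as.data.frame(agg), daily[, c("user_id", "daily_median_hr_bpm",
                                             "daily_median_hrv_ms")],
               by = "user_id")
    data.frame(user_id = m$user_id, axis = axis_name, bin_center_h = m$bin,
               rfd_hr = rfd_ratio(m$median_hr, m$daily_median_hr_bpm, mode),
               rfd_hrv = rfd_ratio(m$median_hrv, m$daily_median_hrv_ms, mode),
               n_windows = m$n_windows, stringsAsFactors = FALSE)
  }

  out <- rbind(align_axis("sleep_onset_s", -15, 9, "hours_from_sleep_onset"),
               align_axis("wake_onset_s", -9, 15, "hours_from_wake_onset"))
  if (is.null(out))
    out <- data.frame(user_id = character(0), axis = character(0),
                      bin_center_h = numeric(0), rfd_hr = numeric(0),
                      rfd_hrv = numeric(0), n_windows = integer(0))
  out <- out[order(out$axis, out$user_id, out$bin_center_h), ]
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  class(out) <- c("sw_rfd", "data.frame")
  out
}

#' @export
print.sw_baseline <- function(x, ...) {
  daily <- attr(x, "daily")
  cat(sprintf("Hourly circadian baseline: %d user(s), %d excluded\n",
              nrow(daily), nrow(attr(x, "excluded"))))
  if (nrow(daily) > 0)
    cat(sprintf("  daily median HR %.1f-%.1f bpm, RMSSD %.1f-%.1f ms\n",
                min(daily$daily_median_hr_bpm), max(daily$daily_median_hr_bpm),
                min(daily$daily_median_hrv_ms), max(daily$daily_median_hrv_ms)))
  NextMethod()
}

#' Plot mean relative-fractional-difference profiles
#'
#' Cross-user mean RFD per bin for one axis, both metrics, base graphics.
#'
#' @param x An `sw_rfd` object.
#' @param axis Which axis to plot (default: the first present).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sw_rfd <- function(x, axis = NULL, ...) {
  if (is.null(axis)) axis <- x$axis[1]
  d <- x[x$axis == axis, ]
  agg_hr <- tapply(d$rfd_hr, d$bin_center_h, mean, na.rm = TRUE)
  agg_hrv <- tapply(d$rfd_hrv, d$bin_center_h, mean, na.rm = TRUE)
  bc <- as.numeric(names(agg_hr))
  graphics::plot(bc, agg_hr, type = "b", pch = 16, col = "firebrick",
                 xlab = axis, ylab = "relative fractional difference",
                 ylim = range(c(agg_hr, agg_hrv), na.rm = TRUE), ...)
  graphics::lines(bc, agg_hrv, type = "b", pch = 17, col = "steelblue")
  graphics::abline(h = 1, lty = 3)
  graphics::legend("topleft", c("HR", "RMSSD"), pch = c(16, 17),
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}
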