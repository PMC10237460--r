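#' Default spline knots for diurnal profiles
#'
#' Segment boundaries (bin centers, hours) used for the piecewise-linear
#' fits to each circadian profile axis and metric.
#'
#' @param axis `"clock_hour"`, `"hours_from_sleep_onset"` or
#'   `"hours_from_wake_onset"`.
#' @param metric `"hr"` or `"hrv"`.
#' @return Numeric vector of knots.
#' @export
default_knots <- function(axis = c("clock_hour", "hours_from_sleep_onset",
                                   "hours_from_wake_onset"),
                          metric = c("hr", "hrv")) {
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  switch(paste(axis, metric),
    "clock_hour hr" = c(0.5, 4.5, 13.5, 19.5, 23.5),
    "clock_hour hrv" = c(0.5, 6.5, 11.5, 17.5, 23.5),
    "hours_from_sleep_onset hr" = c(-14.5, -9.5, -3.5, 6.5, 8.5),
    "hours_from_sleep_onset hrv" = c(-14.5, -11.5, -0.5, 0.5, 8.5),
    "hours_from_wake_onset hr" = c(-8.5, -0.5, 2.5, 12.5, 14.5),
    "hours_from_wake_onset hrv" = c(-8.5, -0.5, 1.5, 4.5, 14.5))
}

#' Continuous piecewise-linear (linear spline) least-squares fit
#'
#' Fits `y` on `x` as a continuous piecewise-linear curve with the given
#' knots (truncated-power basis, ordinary least squares) and reports the
#' slope of each segment with its standard error and a two-sided p-value for
#' slope != 0.
#'
#' @param x Bin centers (e.g. hours); observations outside
#'   `[min(knots), max(knots)]` are dropped.
#' @param y Response (e.g. per user-bin relative fractional differences).
#' @param knots Strictly increasing segment boundaries (first and last span
#'   the data).
#' @return `sw_spline` object: `knots_h`, `segments` data frame
#'   (`from`, `to`, `beta`, `se`, `t`, `p_value`, `n_obs`), `fitted`
#'   data frame, and the underlying `lm` fit.
#' @export
fit_linear_spline <- function(x, y, knots) {
  stopifnot(length(x) == length(y))
  if (is.unsorted(knots, strictly = TRUE))
    stop("knots must be strictly increasing")
  keep <- !is.na(x) & !is.na(y) & x >= knots[1] & x <= knots[length(knots)]
  x <- x[keep]; y <- y[keep]
  K <- length(knots)
  if (K < 2) stop("need at least 2 knots")
  seg_of <- findInterval(x, knots, rightmost.closed = TRUE)
  n_seg <- tabulate(seg_of, nbins = K - 1)
  if (any(n_seg < 2))
    stop(sprintf("empty or underpopulated spline segment [%g, %g]: %d observation(s)",
                 knots[which(n_seg < 2)[1]], knots[which(n_seg < 2)[1] + 1],
                 n_seg[which(n_seg < 2)[1]]))

  basis <- cbind(x, vapply(knots[-c(1, K)], function(k) pmax(x - k, 0),
                           numeric(length(x))))
  colnames(basis) <- c("x", if (K > 2) paste0("h", seq_len(K - 2)))
  fit <- lm(y ~ basis)
  b <- coef(fit)[-1]
  # vcov routes through summary.lm, which warns on noiseless (exact) fits
  V <- suppressWarnings(vcov(fit))[-1, -1, drop = FALSE]
  df <- fit$df.residual

  # slope of segment j = beta_x + sum of hinge coefficients up to knot j
  slopes <- se <- numeric(K - 1)
  for (j in seq_len(K - 1)) {
    cvec <- c(1, as.numeric(seq_len(K - 2) < j))
    slopes[j] <- sum(cvec * b)
    se[j] <- sqrt(drop(t(cvec) %*% V %*% cvec))
  }
  tval <- slopes / se
  segments <- data.frame(from = knots[-K], to = knots[-1], beta = slopes,
                         se = se, t = tval,
                         p_value = 2 * pt(-abs(tval), df), n_obs = n_seg)
  out <- list(knots_h = knots, segments = segments,
              fitted = data.frame(x = x, y = y, fitted = fitted(fit)),
              fit = fit, df = df)
  class(out) <- "sw_spline"
  out
}

#' @export
print.sw_spline <- function(x, digits = 4, ...) {
  cat(sprintf("Linear spline fit: %d segments, %d observations\n",
              nrow(x$segments), nrow(x$fitted)))
  s <- x$segments
  for (j in seq_len(nrow(s)))
    cat(sprintf("  [%6.1f, %6.1f]  beta = %+.*f (se %.1e)  P = %.2e  (n=%d)\n",
                s$from[j], s$to[j], digits, s$beta[j], s$se[j], s$p_value[j],
                s$n_obs[j]))
  invisible(x)
}

#' Predicted values from a linear spline fit
#'
#' @param object An `sw_spline`.
#' @param newdata Optional numeric vector of x values (defaults to the
#'   training x).
#' @param ... Ignored.
#' @return Numeric vector of fitted values.
#' @export
predict.sw_spline <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted$fitted)
  knots <- object$knots_h
  K <- length(knots)
  basis <- cbind(1, newdata,
                 vapply(knots[-c(1, K)], function(k) pmax(newdata - k, 0),
                        numeric(length(newdata))))
  drop(basis %*% coef(object$fit))
}

# Equicoordinate two-sided multivariate-t probabilities by Monte Carlo: one
# sample of the max-|T| null distribution prices every contrast (standard
# error ~1e-3 at 6e4 draws, comparable to quasi-MC quadrature of the same
# integral).
dunnett_adjusted_p <- function(tval, corr, df, n_draws = 60000) {
  draws <- mvtnorm::rmvt(n_draws, sigma = corr, df = as.integer(df))
  maxabs <- abs(draws[, 1])
  for (j in seq_len(ncol(draws))[-1]) maxabs <- pmax(maxabs, abs(draws[, j]))
  vapply(tval, function(tj) {
    if (!is.finite(tj)) return(NA_real_)
    mean(maxabs >= abs(tj))
  }, numeric(1))
}

#' Mixed-model Dunnett comparison of post-event bins against Pre
#'
#' Fits a linear mixed model to one metric's double-normalized deviations
#' (`deviation ~ bin` with a random intercept per user) and compares every
#' During/post bin against the pre-event bin with Dunnett many-to-one
#' multivariate-t contrasts. Because the Pre bin is identically 0 by
#' construction of the double normalization, the model is fit on the
#' During/post bins and each contrast tests that bin's mean deviation
#' against 0; the multivariate-t correction runs over all bins jointly using
#' the fixed-effect covariance (which carries the shared-user correlation).
#' Degrees of freedom use a containment approximation
#' (`N - n_bins - n_users + 1`).
#'
#' @param bins An [event_deviation_table()] result, already filtered to one
#'   event type / load group.
#' @param metric `"delta_hr_bpm"` or `"delta_hrv_ms"`.
#' @param alpha Significance level (default 0.05).
#' @return `sw_dunnett` data frame: `bin`, `estimate`, `se`, `t`,
#'   `p_unadjusted`, `p_adjusted`, `significant`, with the Pre control row
#'   first (estimate 0 by construction). Attributes: `metric`, `df`,
#'   `n_users`, `n_events`.
#' @export
dunnett_vs_pre <- function(bins, metric = c("delta_hr_bpm", "delta_hrv_ms"),
                           alpha = 0.05) {
  metric <- match.arg(metric)
  d <- bins[bins$bin_label != "Pre", ]
  d <- d[!is.na(d[[metric]]), ]
  if (length(unique(d$user_id)) < 2)
    stop("inference error: Dunnett comparison needs at least 2 users")
  labels <- c(if ("During" %in% d$bin_label) "During",
              post_bin_labels(length(unique(grep("^[0-9]", d$bin_label,
                                                 value = TRUE)))))
  labels <- intersect(c("During", post_bin_labels(99)), unique(d$bin_label))
  d$bin <- factor(d$bin_label, levels = labels)
  d$value <- d[[metric]]
  if (nlevels(d$bin) < 1) stop("inference error: no post-event bins")

  fit <- lme4::lmer(value ~ 0 + bin + (1 | user_id), data = d,
                    control = lme4::lmerControl(check.conv.singular =
                                                  lme4::.makeCC(action = "ignore",
                                                                tol = 1e-4)))
  est <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  se <- sqrt(diag(V))
  tval <- est / se
  n_users <- length(unique(d$user_id))
  df <- max(nrow(d) - length(est) - n_users + 1, 2)
  corr <- cov2cor(V)
  p_adj <- dunnett_adjusted_p(tval, corr, df)
  p_un <- 2 * pt(-abs(tval), df)

  out <- data.frame(bin = c("Pre", labels),
                    estimate = c(0, unname(est)),
                    se = c(NA, unname(se)), t = c(NA, unname(tval)),
                    p_unadjusted = c(NA, unname(p_un)),
                    p_adjusted = c(NA, unname(p_adj)),
                    stringsAsFactors = FALSE)
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  attr(out, "metric") <- metric
  attr(out, "df") <- df
  attr(out, "n_users") <- n_users
  attr(out, "n_events") <- length(unique(d$event_id))
  attr(out, "alpha") <- alpha
  class(out) <- c("sw_dunnett", "data.frame")
  out
}

#' @export
print.sw_dunnett <- function(x, ...) {
  cat(sprintf("Dunnett many-to-one vs Pre: %s, %d events, %d users (df=%d)\n",
              attr(x, "metric"), attr(x, "n_events"), attr(x, "n_users"),
              attr(x, "df")))
  NextMethod()
}

#' Tukey comparison of event AUC across run-load groups
#'
#' All-pairs Tukey HSD on per-event areas under the deviation curve, grouped
#' by run load. By default per-event AUCs are averaged within user and group
#' first (one value per user per group) to avoid pseudo-replication; set
#' `per_user_first = FALSE` for raw per-event mode.
#'
#' @param auc An [auc_table()] result (or any frame with `load`, `user_id`
#'   and the metric column).
#' @param metric `"auc_hr"` or `"auc_hrv"`.
#' @param per_user_first Average within user x group before testing.
#' @param alpha Significance level.
#' @return `sw_tukey` data frame: `contrast`, `estimate`, `lwr`, `upr`,
#'   `p_adjusted`, `significant`.
#' @export
tukey_auc_groups <- function(auc, metric = c("auc_hr", "auc_hrv"),
                             per_user_first = TRUE, alpha = 0.05) {
  metric <- match.arg(metric)
  d <- auc[!is.na(auc$load), ]
  d$value <- d[[metric]]
  d <- d[!is.na(d$value), ]
  if (per_user_first) {
    agg <- stats::aggregate(value ~ user_id + load, data = d, FUN = mean)
    d <- agg
  }
  counts <- table(d$load)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    warning("dropping group(s) with < 2 observations: ",
            paste(small, collapse = ", "))
    d <- d[!d$load %in% small, ]
  }
  if (length(unique(d$load)) < 2)
    stop("inference error: Tukey comparison needs at least 2 groups")
  d$load <- factor(d$load,
                   levels = intersect(c("light", "moderate", "vigorous"),
                                      unique(d$load)))
  tk <- TukeyHSD(aov(value ~ load, data = d))$load
  out <- data.frame(contrast = rownames(tk), estimate = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adjusted = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$significant <- out$p_adjusted < alpha
  attr(out, "metric") <- metric
  attr(out, "per_user_first") <- per_user_first
  class(out) <- c("sw_tukey", "data.frame")
  out
}

#' @export
print.sw_tukey <- function(x, ...) {
  cat(sprintf("Tukey HSD on %s across run loads%s\n", attr(x, "metric"),
              if (attr(x, "per_user_first")) " (per-user means)" else ""))
  NextMethod()
}
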