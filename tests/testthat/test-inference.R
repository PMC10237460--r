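test_that("linear data give identical slopes in every spline segment", {
  x <- rep(seq(0.5, 23.5, by = 1), times = 20)
  y <- 1 + 0.01 * x
  fit <- fit_linear_spline(x, y, knots = c(0.5, 4.5, 13.5, 19.5, 23.5))
  expect_equal(fit$segments$beta, rep(0.01, 4), tolerance = 1e-10)
  expect_lt(max(abs(fit$fitted$fitted - fit$fitted$y)), 1e-10)
})

test_that("noiseless piecewise slopes are recovered exactly and continuously", {
  x <- rep(seq(0.5, 19.5, by = 1), times = 5)
  knots <- c(0, 10, 20)
  y <- ifelse(x < 10, 1 - 0.02 * x, 1 - 0.2 + 0.03 * (x - 10))
  fit <- fit_linear_spline(x, y, knots)
  expect_equal(fit$segments$beta, c(-0.02, 0.03), tolerance = 1e-10)
  # continuity at the knot
  left <- predict(fit, 10 - 1e-9)
  right <- predict(fit, 10 + 1e-9)
  expect_equal(left, right, tolerance = 1e-6)
})

test_that("spline fit is invariant to observation order and flags empty segments", {
  set.seed(31)
  x <- rep(seq(0.5, 23.5), times = 8)
  y <- sin(x / 4) + rnorm(length(x), 0, 0.05)
  knots <- c(0.5, 8.5, 16.5, 23.5)
  f1 <- fit_linear_spline(x, y, knots)
  idx <- sample(length(x))
  f2 <- fit_linear_spline(x[idx], y[idx], knots)
  expect_equal(f1$segments$beta, f2$segments$beta, tolerance = 1e-12)
  expect_error(fit_linear_spline(c(1, 2, 9), c(0, 0, 0), c(0, 4, 8, 12)),
               "segment")
})

test_that("spline slope inference is calibrated against its standard errors", {
  # Monte-Carlo: with iid noise the reported 2-SE band covers the generating
  # slope in roughly 95% of replicates
  slopes_true <- c(-0.014, 0.025)
  knots <- c(0.5, 9.5, 23.5)
  xs <- seq(0.5, 23.5)
  gen_y <- function(x) ifelse(x < 9.5, 1 + slopes_true[1] * (x - 0.5),
                              1 + slopes_true[1] * 9 + slopes_true[2] * (x - 9.5))
  set.seed(77)
  hits <- replicate(200, {
    x <- rep(xs, times = 12)
    y <- gen_y(x) + rnorm(length(x), 0, 0.02)
    s <- fit_linear_spline(x, y, knots)$segments
    all(abs(s$beta - slopes_true) < 2 * s$se)
  })
  expect_gte(mean(hits), 0.85)
})

# deviation-bin fixture: n_users users x n_ev events each, iid noise plus an
# optional per-bin offset vector
sim_bins_table <- function(n_users, n_ev, offsets, sd = 1, sd_user = 0.3,
                           seed = 1) {
  set.seed(seed)
  labels <- sprintf("%d-%d", seq(0, 270, 30), seq(30, 300, 30))
  rows <- expand.grid(user = seq_len(n_users), ev = seq_len(n_ev),
                      bin = seq_along(labels))
  u_eff <- rnorm(n_users, 0, sd_user)
  data.frame(
    event_id = sprintf("u%d_e%d", rows$user, rows$ev),
    user_id = sprintf("u%d", rows$user),
    bin_label = labels[rows$bin],
    bin_center_s = rows$bin * 1800 - 900,
    delta_hr_bpm = offsets[rows$bin] + u_eff[rows$user] +
      rnorm(nrow(rows), 0, sd),
    delta_hrv_ms = 0, n_windows = 10L, type = "run", load = "moderate",
    stringsAsFactors = FALSE)
}

test_that("Dunnett adjustment is conservative relative to raw p-values", {
  d <- sim_bins_table(8, 3, offsets = rep(0, 10), seed = 11)
  res <- dunnett_vs_pre(d, "delta_hr_bpm")
  post <- res[res$bin != "Pre", ]
  expect_true(all(post$p_adjusted >= post$p_unadjusted - 1e-12))
  expect_true(all(post$p_adjusted >= 0 & post$p_adjusted <= 1))
  expect_equal(res$estimate[res$bin == "Pre"], 0)
})

test_that("null deviations are rarely declared significant", {
  # family-wise: the fraction of null tables with any significant bin should
  # sit near the nominal 5% (checked tightly in the acceptance suite)
  any_sig <- vapply(1:20, function(s) {
    d <- sim_bins_table(8, 3, offsets = rep(0, 10), seed = 600 + s)
    any(dunnett_vs_pre(d, "delta_hr_bpm")$significant)
  }, logical(1))
  expect_lte(mean(any_sig), 0.25)
})

test_that("the hand-rolled multivariate-t Dunnett matches multcomp", {
  skip_if_not_installed("multcomp")
  d <- sim_bins_table(12, 2, offsets = c(2, 1.5, 1, 0.5, rep(0, 6)), seed = 41)
  res <- dunnett_vs_pre(d, "delta_hr_bpm")
  post <- res[res$bin != "Pre", ]
  # same estimates/covariance handed to multcomp's single-step machinery
  dd <- d[!is.na(d$delta_hr_bpm), ]
  dd$bin <- factor(dd$bin_label, levels = unique(d$bin_label))
  fit <- lme4::lmer(delta_hr_bpm ~ 0 + bin + (1 | user_id), data = dd)
  gl <- multcomp::glht(multcomp::parm(lme4::fixef(fit),
                                      as.matrix(vcov(fit)),
                                      df = attr(res, "df")),
                       linfct = diag(10))
  p_mc <- summary(gl, test = multcomp::adjusted("single-step"))$test$pvalues
  expect_equal(unname(post$p_adjusted), unname(as.numeric(p_mc)),
               tolerance = 5e-3)
  expect_equal(unname(post$estimate), unname(lme4::fixef(fit)),
               tolerance = 1e-8)
})

test_that("Dunnett refuses degenerate designs", {
  d <- sim_bins_table(1, 3, offsets = rep(0, 10))
  expect_error(dunnett_vs_pre(d, "delta_hr_bpm"), "at least 2 users")
})

auc_fixture <- function(effects = c(light = 0, moderate = 120, vigorous = 240),
                        n_users = 12, sd = 20, seed = 5) {
  set.seed(seed)
  rows <- expand.grid(user = seq_len(n_users), load = names(effects),
                      ev = 1:2, stringsAsFactors = FALSE)
  data.frame(event_id = sprintf("%s_%s_%d", rows$user, rows$load, rows$ev),
             user_id = sprintf("u%d", rows$user), type = "run",
             load = rows$load,
             auc_hr = effects[rows$load] + rnorm(nrow(rows), 0, sd),
             auc_hrv = -effects[rows$load] + rnorm(nrow(rows), 0, sd),
             stringsAsFactors = FALSE)
}

test_that("Tukey recovers a clean dose-response ordering", {
  a <- auc_fixture()
  tk <- tukey_auc_groups(a, "auc_hr")
  expect_equal(nrow(tk), 3)
  expect_true(all(tk$significant))
  est <- tk$estimate
  names(est) <- tk$contrast
  expect_gt(est[["moderate-light"]], 0)
  expect_gt(est[["vigorous-light"]], 0)
  expect_gt(est[["vigorous-moderate"]], 0)
  # antisymmetric on the HRV side
  tkv <- tukey_auc_groups(a, "auc_hrv")
  expect_lt(tkv$estimate[tkv$contrast == "vigorous-light"], 0)
})

test_that("identical distributions are rarely declared different", {
  a <- auc_fixture(effects = c(light = 100, moderate = 100, vigorous = 100),
                   seed = 8)
  tk <- tukey_auc_groups(a, "auc_hr")
  expect_false(any(tk$significant))
})

test_that("two-group Tukey equals the pooled two-sample t-test", {
  a <- auc_fixture()
  a <- a[a$load != "vigorous", ]
  tk <- tukey_auc_groups(a, "auc_hr", per_user_first = FALSE)
  expect_equal(nrow(tk), 1)
  tt <- t.test(auc_hr ~ load, data = a, var.equal = TRUE)
  expect_equal(tk$p_adjusted, tt$p.value, tolerance = 1e-6)
})

test_that("undersized groups are dropped with a warning", {
  a <- auc_fixture()
  a <- a[a$load != "light" | a$event_id == a$event_id[a$load == "light"][1], ]
  expect_warning(tk <- tukey_auc_groups(a, "auc_hr", per_user_first = FALSE),
                 "dropping")
  expect_equal(nrow(tk), 1)
})
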