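#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Instantaneous HR (bpm) / RMSSD target (ms) at time t (seconds from cohort
// epoch): single-harmonic circadian sinusoid plus event offsets.
//
// events matrix columns:
//   0 start_s, 1 end_s,
//   2 post_delta_hr_bpm, 3 tau_hr_s, 4 post_delta_hrv_ms, 5 tau_hrv_s,
//   6 during_delta_hr_bpm, 7 during_delta_hrv_ms
// Post-event offsets decay exponentially from the event END; during-event
// offsets are constant on [start, end].
static inline double circ(double t, double mesor, double amp, double peak_h) {
  double d = t / 86400.0;
  double h = (d - std::floor(d)) * 24.0;  // hour of day, no DST
  return mesor + amp * std::cos(2.0 * M_PI * (h - peak_h) / 24.0);
}

static inline double event_offset(double t, const NumericMatrix& ev,
                                  int col_post, int col_tau, int col_during) {
  double off = 0.0;
  for (int i = 0; i < ev.nrow(); ++i) {
    double start = ev(i, 0), end = ev(i, 1);
    if (t > end) {
      double delta = ev(i, col_post), tau = ev(i, col_tau);
      // 40*tau cutoff: the residual is below delta * 4e-18
      if (delta != 0.0 && t - end < 40.0 * tau)
        off += delta * std::exp(-(t - end) / tau);
    } else if (t >= start) {
      off += ev(i, col_during);
    }
  }
  return off;
}

// [[Rcpp::export]]
List cpp_simulate_rr(double t0, double t_end,
                     double hr_mesor, double hr_amp, double hr_peak_h,
                     double hrv_mesor, double hrv_amp, double hrv_peak_h,
                     NumericMatrix events, bool noise) {
  const double sqrt2 = std::sqrt(2.0);
  std::vector<double> times, rrs;
  size_t guess = (size_t)((t_end - t0) * (hr_mesor + hr_amp) / 60.0) + 16;
  times.reserve(guess);
  rrs.reserve(guess);

  // The circadian sinusoids are tabulated on a 5-s grid and linearly
  // interpolated (curvature error ~1e-7 bpm); event offsets are evaluated
  // exactly per beat. HR varies by < 1e-4 bpm over one beat, so evaluating
  // the curves at the previous beat time is exact to well below the 0.1-bpm
  // reproduction tolerance of the noiseless stream.
  const double grid = 5.0;
  size_t n_grid = (size_t)((t_end - t0) / grid) + 2;
  std::vector<double> hr_tab(n_grid), hrv_tab(n_grid);
  for (size_t g = 0; g < n_grid; ++g) {
    double tg = t0 + grid * (double)g;
    hr_tab[g] = circ(tg, hr_mesor, hr_amp, hr_peak_h);
    hrv_tab[g] = circ(tg, hrv_mesor, hrv_amp, hrv_peak_h);
  }
  const bool flat_hr = hr_amp == 0.0, flat_hrv = hrv_amp == 0.0;
  auto lut = [&](const std::vector<double>& tab, double t) {
    double u = (t - t0) / grid;
    size_t g = (size_t)u;
    if (g + 1 >= n_grid) g = n_grid - 2;
    double w = u - (double)g;
    return tab[g] * (1.0 - w) + tab[g + 1] * w;
  };

  double t = t0;
  while (t < t_end) {
    double hr = (flat_hr ? hr_mesor : lut(hr_tab, t)) +
                event_offset(t, events, 2, 3, 6);
    if (hr <= 0.0)
      stop("circadian HR profile non-positive at t=%.0f s", t);
    if (hr < 25.0 || hr > 220.0)
      stop("HR %.1f bpm at t=%.0f s outside physiological range [25, 220]; "
           "check response_params", hr, t);
    double rr = 60000.0 / hr;
    if (noise) {
      double hrv = (flat_hrv ? hrv_mesor : lut(hrv_tab, t)) -
                   event_offset(t, events, 4, 5, 7);
      if (hrv < 1.0) hrv = 1.0;  // physiological floor during responses
      rr += R::norm_rand() * hrv / sqrt2;
      if (rr < 200.0) rr = 200.0;  // guard: RR must stay positive
    }
    t += rr / 1000.0;
    if (t > t_end) break;  // the span ends mid-interval: no beat observed
    times.push_back(t);
    rrs.push_back(rr);
  }
  return List::create(_["beat_time_s"] = wrap(times), _["rr_ms"] = wrap(rrs));
}

// Per-window beat statistics over half-open blocks [lo[k], hi[k]) of a
// sorted beat stream: beat count, RR sum, successive-difference count and
// sum of squares (pairs fully inside the block). Two-pointer sweep, O(n+W);
// windows must be sorted by lo with constant width.
// [[Rcpp::export]]
List cpp_window_beat_stats(NumericVector bt, NumericVector rr,
                           NumericVector lo, NumericVector hi) {
  int n = bt.size(), W = lo.size();
  IntegerVector n_beats(W), n_d(W);
  NumericVector sum_rr(W), sum_d2(W);
  int i1 = 0, i2 = 0;  // [i1, i2): beats in current window
  double s_rr = 0.0, s_d2 = 0.0;
  for (int k = 0; k < W; ++k) {
    while (i1 < n && bt[i1] < lo[k]) {
      s_rr -= rr[i1];
      if (i1 + 1 < i2) s_d2 -= (rr[i1 + 1] - rr[i1]) * (rr[i1 + 1] - rr[i1]);
      ++i1;
    }
    if (i2 < i1) { i2 = i1; s_rr = 0.0; s_d2 = 0.0; }
    while (i2 < n && bt[i2] < hi[k]) {
      s_rr += rr[i2];
      if (i2 > i1) s_d2 += (rr[i2] - rr[i2 - 1]) * (rr[i2] - rr[i2 - 1]);
      ++i2;
    }
    n_beats[k] = i2 - i1;
    n_d[k] = i2 > i1 ? i2 - i1 - 1 : 0;
    sum_rr[k] = s_rr;
    sum_d2[k] = s_d2;
  }
  return List::create(_["n_beats"] = n_beats, _["sum_rr"] = sum_rr,
                      _["n_d"] = n_d, _["sum_d2"] = sum_d2);
}

// Per-window counts of motion samples and of samples exceeding the motion
// threshold, same half-open convention.
// [[Rcpp::export]]
List cpp_window_motion_counts(NumericVector mt, LogicalVector exceed,
                              NumericVector lo, NumericVector hi) {
  int n = mt.size(), W = lo.size();
  IntegerVector n_m(W), n_ex(W);
  int i1 = 0, i2 = 0, ex = 0;
  for (int k = 0; k < W; ++k) {
    while (i1 < n && mt[i1] < lo[k]) {
      if (exceed[i1]) --ex;
      ++i1;
    }
    if (i2 < i1) { i2 = i1; ex = 0; }
    while (i2 < n && mt[i2] < hi[k]) {
      if (exceed[i2]) ++ex;
      ++i2;
    }
    n_m[k] = i2 - i1;
    n_ex[k] = ex;
  }
  return List::create(_["n_samples"] = n_m, _["n_exceed"] = n_ex);
}

// True (noise-free) HR and RMSSD-target curves at arbitrary times.
// [[Rcpp::export]]
List cpp_true_curves(NumericVector t,
                     double hr_mesor, double hr_amp, double hr_peak_h,
                     double hrv_mesor, double hrv_amp, double hrv_peak_h,
                     NumericMatrix events) {
  int n = t.size();
  NumericVector hr(n), hrv(n);
  for (int i = 0; i < n; ++i) {
    hr[i] = circ(t[i], hr_mesor, hr_amp, hr_peak_h) +
            event_offset(t[i], events, 2, 3, 6);
    double v = circ(t[i], hrv_mesor, hrv_amp, hrv_peak_h) -
               event_offset(t[i], events, 4, 5, 7);
    hrv[i] = v < 1.0 ? 1.0 : v;
  }
  return List::create(_["hr_bpm"] = hr, _["rmssd_ms"] = hrv);
}
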