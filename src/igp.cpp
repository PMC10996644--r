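#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Inhomogeneous-gamma-process estimation kernels.
//
// Data layout shared by the routines below: rewards from all patches are
// concatenated into `times` (times measured from each patch's own entry),
// with patch m occupying the half-open index range
// [offsets[m], offsets[m+1]) and observed for durations[m] seconds.
// lam(t) = lam0 * exp(-t/tau); every L-th hidden Poisson event is a reward.
//
// Gamma priors Gamma(al, bl) on lam0 and Gamma(at, bt) on tau; the pair
// (al = 1, bl = 0, at = 1, bt = 0) recovers the plain likelihood.

// Stationarity equation g(tau) = d/dtau log posterior, with lam0 profiled
// out via its own stationarity condition
//   lam0(tau) = (L * sum(K_m) + al - 1) / (sum_m tau (1 - e^{-T_m/tau}) + bl).
static double g_tau(double tau,
                    const double *times, const int *offsets, int n_patches,
                    const double *durations, int L,
                    double al, double bl, double at, double bt) {
  double A = 0.0, B = 0.0, sum_t = 0.0, sum_alpha = 0.0;
  double total_K = 0.0;
  for (int m = 0; m < n_patches; ++m) {
    const double T = durations[m];
    const double eT = std::exp(-T / tau);
    A += tau * (1.0 - eT);
    B += T * eT;
    double prev = 0.0;
    for (int j = offsets[m]; j < offsets[m + 1]; ++j) {
      const double tk = times[j];
      sum_t += tk;
      if (L > 1) {
        double d = tk - prev;
        if (d < 1e-12) d = 1e-12;
        const double ed = std::exp(-d / tau);
        // alpha(t_{k-1}, t_k) = (t_{k-1} e^{-t_{k-1}/tau} - t_k e^{-t_k/tau})
        //                       / (e^{-t_{k-1}/tau} - e^{-t_k/tau})
        sum_alpha += (prev - tk * ed) / (1.0 - ed);
      }
      prev = tk;
      total_K += 1.0;
    }
  }
  const double lam0 = (L * total_K + al - 1.0) / (A + bl);
  return -(lam0 / tau) * (A - B)
    + (L - 1.0) * total_K / tau
    + (L - 1.0) * sum_alpha / (tau * tau)
    + sum_t / (tau * tau)
    + (at - 1.0) / tau - bt;
}

// Bracket a sign change of g and solve by the Illinois variant of regula
// falsi (superlinear, bracket-safe). Returns NA_REAL if no bracket is
// found (possible for the pure likelihood on near-homogeneous data).
// `seed` (> 0) warm-starts the bracket around a previous solution.
static double solve_tau(const double *times, const int *offsets, int n_patches,
                        const double *durations, int L,
                        double al, double bl, double at, double bt,
                        double lo, double hi, double seed = -1.0) {
  const auto g = [&](double tau) {
    return g_tau(tau, times, offsets, n_patches, durations, L, al, bl, at, bt);
  };
  double glo, ghi;
  bool bracketed = false;
  if (seed > 0.0) {
    double l = seed * 0.5, h = seed * 2.0;
    const double gl = g(l), gh = g(h);
    if (gl > 0.0 && gh < 0.0) {
      lo = l; hi = h; glo = gl; ghi = gh; bracketed = true;
    }
  }
  if (!bracketed) {
    glo = g(lo);
    int it = 0;
    while (glo <= 0.0 && it++ < 60) { lo /= 2.0; glo = g(lo); }
    if (glo <= 0.0) return NA_REAL;
    ghi = g(hi);
    it = 0;
    while (ghi >= 0.0 && it++ < 60) { hi *= 2.0; ghi = g(hi); }
    if (ghi >= 0.0) return NA_REAL;
  }
  for (int i = 0; i < 100 && (hi - lo) > 1e-10 * (1.0 + hi); ++i) {
    double x = (lo * ghi - hi * glo) / (ghi - glo);
    if (!(x > lo && x < hi)) x = 0.5 * (lo + hi);
    const double gx = g(x);
    if (gx == 0.0) return x;
    if (gx > 0.0) {
      lo = x; glo = gx; ghi *= 0.5;  // Illinois damping on the stale end
    } else {
      hi = x; ghi = gx; glo *= 0.5;
    }
  }
  return 0.5 * (lo + hi);
}

static double lam0_profile(double tau,
                           const double *times, const int *offsets,
                           int n_patches, const double *durations, int L,
                           double al, double bl) {
  double A = 0.0, total_K = 0.0;
  for (int m = 0; m < n_patches; ++m) {
    A += tau * (1.0 - std::exp(-durations[m] / tau));
    total_K += offsets[m + 1] - offsets[m];
  }
  return (L * total_K + al - 1.0) / (A + bl);
}

// [[Rcpp::export]]
double cpp_g_tau(double tau, NumericVector times, IntegerVector offsets,
                 NumericVector durations, int L,
                 double al, double bl, double at, double bt) {
  return g_tau(tau, REAL(times), INTEGER(offsets), durations.size(),
               REAL(durations), L, al, bl, at, bt);
}

// [[Rcpp::export]]
double cpp_solve_tau(NumericVector times, IntegerVector offsets,
                     NumericVector durations, int L,
                     double al, double bl, double at, double bt,
                     double lo = 1e-3, double hi = 100.0) {
  return solve_tau(REAL(times), INTEGER(offsets), durations.size(),
                   REAL(durations), L, al, bl, at, bt, lo, hi);
}

// Shared workhorse for the online estimator: history patches are fixed;
// the current patch's observation window grows bin by bin (t_i = i * dt),
// including only rewards observed up to t_i. Writes the rate estimate at
// each bin into `trace` (if non-null). If lambda_star >= 0, returns the
// first bin time whose estimate is <= lambda_star (ties fire), else -1.
static double estimator_loop(const NumericVector &cur_rewards,
                             const NumericVector &hist_times,
                             const IntegerVector &hist_offsets,
                             const NumericVector &hist_durations,
                             int L, double al, double bl, double at, double bt,
                             double dt, double t_max, double lambda_star,
                             NumericVector *trace) {
  const int n_hist = hist_durations.size();
  const int n_cur = cur_rewards.size();
  const int n_bins = (int)std::floor(t_max / dt + 1e-9);

  std::vector<double> times(hist_times.begin(), hist_times.end());
  times.resize(hist_times.size() + n_cur);
  std::vector<int> offsets(hist_offsets.begin(), hist_offsets.end());
  offsets.push_back(0);  // current patch end; updated per bin
  std::vector<double> durations(hist_durations.begin(), hist_durations.end());
  durations.push_back(0.0);

  const int base = hist_times.size();
  const double tau_mode = (at > 1.0 && bt > 0.0) ? (at - 1.0) / bt : 1.0;
  int p = 0;
  double prev_tau = -1.0;
  for (int i = 1; i <= n_bins; ++i) {
    const double ti = i * dt;
    while (p < n_cur && cur_rewards[p] <= ti + 1e-9) {
      times[base + p] = cur_rewards[p];
      ++p;
    }
    offsets[n_hist + 1] = base + p;
    durations[n_hist] = ti;
    double tau = solve_tau(times.data(), offsets.data(), n_hist + 1,
                           durations.data(), L, al, bl, at, bt,
                           1e-3, 10.0 * std::max(tau_mode, ti), prev_tau);
    if (std::isfinite(tau)) prev_tau = tau;
    if (!std::isfinite(tau)) tau = tau_mode;  // proper priors: should not occur
    const double lam0 = lam0_profile(tau, times.data(), offsets.data(),
                                     n_hist + 1, durations.data(), L, al, bl);
    const double lam_t = lam0 * std::exp(-ti / tau);
    if (trace) (*trace)[i - 1] = lam_t;
    if (lambda_star >= 0.0 && lam_t <= lambda_star) return ti;
  }
  return -1.0;
}

// [[Rcpp::export]]
NumericVector cpp_rate_trace(NumericVector cur_rewards,
                             NumericVector hist_times,
                             IntegerVector hist_offsets,
                             NumericVector hist_durations,
                             int L, double al, double bl, double at, double bt,
                             double dt, double t_max) {
  const int n_bins = (int)std::floor(t_max / dt + 1e-9);
  NumericVector trace(n_bins);
  estimator_loop(cur_rewards, hist_times, hist_offsets, hist_durations,
                 L, al, bl, at, bt, dt, t_max, -1.0, &trace);
  return trace;
}

// [[Rcpp::export]]
double cpp_predict_crossing(NumericVector cur_rewards,
                            NumericVector hist_times,
                            IntegerVector hist_offsets,
                            NumericVector hist_durations,
                            int L, double al, double bl, double at, double bt,
                            double lambda_star, double dt, double t_max) {
  return estimator_loop(cur_rewards, hist_times, hist_offsets, hist_durations,
                        L, al, bl, at, bt, dt, t_max, lambda_star, NULL);
}

// First bin (i * dt) at which trace[i-1] <= lambda_star; -1 if none.
// [[Rcpp::export]]
double cpp_first_crossing(NumericVector trace, double lambda_star, double dt) {
  for (int i = 0; i < trace.size(); ++i)
    if (trace[i] <= lambda_star) return (i + 1) * dt;
  return -1.0;
}

// Vectorized crossing scan over a list of traces; entries with no
// crossing return the corresponding t_max.
// [[Rcpp::export]]
NumericVector cpp_first_crossing_many(List traces, NumericVector lambda_star,
                                      double dt, NumericVector t_max) {
  const int n = traces.size();
  NumericVector out(n);
  for (int j = 0; j < n; ++j) {
    NumericVector tr = traces[j];
    double t = -1.0;
    const double thr = lambda_star[j];
    for (int i = 0; i < tr.size(); ++i)
      if (tr[i] <= thr) { t = (i + 1) * dt; break; }
    out[j] = (t < 0) ? t_max[j] : t;
  }
  return out;
}
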