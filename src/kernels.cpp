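#include <Rcpp.h>
using namespace Rcpp;

// Piecewise-linear interpolation through monotone join-points (xk, yk).
// Values outside [xk[0], xk[last]] are clamped to the endpoints.
static inline double pl_interp(const double *xk, const double *yk,
                               const int nk, const double t) {
  if (t <= xk[0]) return yk[0];
  if (t >= xk[nk - 1]) return yk[nk - 1];
  int lo = 0, hi = nk - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (xk[mid] <= t) lo = mid; else hi = mid;
  }
  double w = (t - xk[lo]) / (xk[hi] - xk[lo]);
  return yk[lo] + w * (yk[hi] - yk[lo]);
}

// [[Rcpp::export]]
NumericVector piecewise_linear(NumericVector xk, NumericVector yk,
                               NumericVector t) {
  int nk = xk.size();
  if (nk != yk.size() || nk < 2) stop("bad join-points");
  NumericVector out(t.size());
  for (int i = 0; i < t.size(); ++i)
    out[i] = pl_interp(xk.begin(), yk.begin(), nk, t[i]);
  return out;
}

static inline int bin_of(double t, double dt, int n_bins) {
  int b = (int)std::floor(t / dt);
  if (b < 0) b = 0;
  if (b >= n_bins) b = n_bins - 1;  // clamp numerical edge cases
  return b;
}

// Linear interpolation of a template stored on bin midpoints (k + 0.5) dt,
// clamped at the ends.
static inline double grid_interp(const double *f, int n_bins, double dt,
                                 double t) {
  double x = t / dt - 0.5;
  if (x <= 0) return f[0];
  if (x >= n_bins - 1) return f[n_bins - 1];
  int k = (int)std::floor(x);
  double w = x - k;
  return f[k] + w * (f[k + 1] - f[k]);
}

// Bin spike times into half-open bins [k*dt, (k+1)*dt); a spike exactly at
// T = n_bins*dt is dropped.
// [[Rcpp::export]]
IntegerVector bin_counts_cpp(NumericVector times, int n_bins, double dt) {
  IntegerVector out(n_bins);
  for (int i = 0; i < times.size(); ++i) {
    double t = times[i];
    if (t < 0 || t > n_bins * dt) stop("spike time outside [0, T]");
    if (t == n_bins * dt) continue;
    out[(int)std::floor(t / dt)]++;
  }
  return out;
}

// Warped template on the trial-time bin grid: fw[j] = f(phi^{-1}(u_j)) with
// u_j the trial bin midpoints, (xk, yk) the inverse warp's join-points
// (trial time -> template time), and f interpolated linearly between its
// grid values. Smooth in the peak shifts.
// [[Rcpp::export]]
NumericVector warp_template_cpp(NumericVector f, NumericVector xk,
                                NumericVector yk, double dt) {
  int n_bins = f.size();
  int nk = xk.size();
  NumericVector out(n_bins);
  for (int j = 0; j < n_bins; ++j) {
    double uj = (j + 0.5) * dt;
    double tw = pl_interp(xk.begin(), yk.begin(), nk, uj);
    out[j] = grid_interp(f.begin(), n_bins, dt, tw);
  }
  return out;
}

// Discretized point-process log-likelihood: sum y log(mu) - mu - log(y!).
// [[Rcpp::export]]
double pp_loglik_cpp(IntegerVector y, NumericVector mu) {
  if (y.size() != mu.size()) stop("length mismatch");
  double s = 0.0;
  for (int k = 0; k < y.size(); ++k) {
    if (mu[k] <= 0) stop("intensity must be strictly positive");
    if (y[k] > 0) s += y[k] * std::log(mu[k]) - std::lgamma(y[k] + 1.0);
    s -= mu[k];
  }
  return s;
}

// Merged-group log-likelihood of one trial under the warped template model:
// mu_j = N exp(f(phi^{-1}(u_j)) + gain) dt_s on the trial-time grid, raw
// binned counts y. (xk, yk) are the inverse warp's join-points; pass the
// identity (e.g. c(0, T) twice) for unwarped groups. Includes the
// count-factorial constants so values are comparable across groups.
// [[Rcpp::export]]
double group_loglik_cpp(IntegerVector y, NumericVector xk, NumericVector yk,
                        NumericVector f, double gain, double N,
                        double dt_ms) {
  int n_bins = y.size();
  if (f.size() != n_bins) stop("length mismatch");
  double dt_s = dt_ms / 1000.0;
  double log_const = std::log(N * dt_s) + gain;
  double eg = std::exp(gain);
  int nk = xk.size();
  double s = 0.0;
  for (int j = 0; j < n_bins; ++j) {
    double uj = (j + 0.5) * dt_ms;
    double fw = grid_interp(f.begin(), n_bins, dt_ms,
                            pl_interp(xk.begin(), yk.begin(), nk, uj));
    s -= N * dt_s * eg * std::exp(fw);
    if (y[j] > 0)
      s += y[j] * (fw + log_const) - std::lgamma(y[j] + 1.0);
  }
  return s;
}

// Per-neuron log-likelihoods (exposure 1) under a common warp and template:
// each neuron's raw binned train scored against exp(f(phi^{-1}(u_j)) + gain)
// dt_s. neuron is 1-based. The integral and warped template are shared
// across neurons; per-neuron spike terms are accumulated from spike times.
// [[Rcpp::export]]
NumericVector neuron_logliks_cpp(NumericVector times, IntegerVector neuron,
                                 int n_neurons, NumericVector xk,
                                 NumericVector yk, NumericVector f,
                                 double gain, double dt_ms) {
  int n_bins = f.size();
  double dt_s = dt_ms / 1000.0;
  double log_const = std::log(dt_s) + gain;
  int nk = xk.size();
  std::vector<double> fw(n_bins);
  double integ = 0.0;
  for (int j = 0; j < n_bins; ++j) {
    double uj = (j + 0.5) * dt_ms;
    fw[j] = grid_interp(f.begin(), n_bins, dt_ms,
                        pl_interp(xk.begin(), yk.begin(), nk, uj));
    integ += std::exp(fw[j]);
  }
  double base = -dt_s * std::exp(gain) * integ;
  NumericVector out(n_neurons, base);
  if (times.size() == 0) return out;
  std::vector<std::pair<int, int> > keys(times.size());
  int nkeys = 0;
  for (int i = 0; i < times.size(); ++i) {
    int n = neuron[i] - 1;
    if (n < 0 || n >= n_neurons) stop("neuron index out of range");
    if (times[i] >= n_bins * dt_ms) continue;
    int j = bin_of(times[i], dt_ms, n_bins);
    out[n] += fw[j] + log_const;
    keys[nkeys++] = std::make_pair(n, j);
  }
  keys.resize(nkeys);
  std::sort(keys.begin(), keys.end());
  // factorial corrections where a (neuron, bin) holds more than one spike
  int run = 1;
  for (size_t i = 1; i <= keys.size(); ++i) {
    if (i < keys.size() && keys[i] == keys[i - 1]) { run++; continue; }
    if (run > 1) out[keys[i - 1].first] -= std::lgamma(run + 1.0);
    run = 1;
  }
  return out;
}

// Warped sufficient statistics of one trial for the template M-step on the
// template grid: yw[k] = counts of spikes with phi^{-1}(s) in template bin
// k, and occupancy u[k] = number of trial bin midpoints mapping to template
// bin k (the discrete bin-time weights of the trial-time integral).
// (xk, yk) are the inverse warp's join-points.
// [[Rcpp::export]]
List warp_suffstats_cpp(NumericVector times, NumericVector xk,
                        NumericVector yk, int n_bins, double dt) {
  IntegerVector yw(n_bins), u(n_bins);
  int nk = xk.size();
  for (int i = 0; i < times.size(); ++i) {
    if (times[i] >= n_bins * dt) continue;
    double w = pl_interp(xk.begin(), yk.begin(), nk, times[i]);
    yw[bin_of(w, dt, n_bins)]++;
  }
  for (int j = 0; j < n_bins; ++j) {
    double uj = (j + 0.5) * dt;
    u[bin_of(pl_interp(xk.begin(), yk.begin(), nk, uj), dt, n_bins)]++;
  }
  return List::create(Named("yw") = yw, Named("u") = u);
}

// All three group log-likelihoods for every neuron of one trial in one
// pass: column 1 scores against the warped population template (inverse
// warp join-points (xk, yk), trial gain), columns 2-3 against the unwarped
// local templates. Shared count-factorial constants are included in every
// column (they cancel in membership probabilities but keep the values
// comparable as absolute log-likelihoods).
// [[Rcpp::export]]
NumericMatrix neuron_logliks3_cpp(NumericVector times, IntegerVector neuron,
                                  int n_neurons, NumericVector xk,
                                  NumericVector yk, NumericVector f_pop,
                                  double gain, NumericVector f_l1,
                                  double lograte_l2, double dt_ms) {
  int n_bins = f_pop.size();
  double dt_s = dt_ms / 1000.0;
  int nk = xk.size();
  std::vector<double> fw(n_bins);
  double integ_pop = 0.0, integ_l1 = 0.0;
  for (int j = 0; j < n_bins; ++j) {
    double uj = (j + 0.5) * dt_ms;
    fw[j] = grid_interp(f_pop.begin(), n_bins, dt_ms,
                        pl_interp(xk.begin(), yk.begin(), nk, uj));
    integ_pop += std::exp(fw[j]);
    integ_l1 += std::exp(f_l1[j]);
  }
  NumericMatrix out(n_neurons, 3);
  double base_pop = -dt_s * std::exp(gain) * integ_pop;
  double base_l1 = -dt_s * integ_l1;
  double base_l2 = -dt_s * n_bins * std::exp(lograte_l2);
  for (int n = 0; n < n_neurons; ++n) {
    out(n, 0) = base_pop;
    out(n, 1) = base_l1;
    out(n, 2) = base_l2;
  }
  if (times.size() == 0) return out;
  double lc = std::log(dt_s);
  std::vector<std::pair<int, int> > keys(times.size());
  int nkeys = 0;
  for (int i = 0; i < times.size(); ++i) {
    int n = neuron[i] - 1;
    if (n < 0 || n >= n_neurons) stop("neuron index out of range");
    if (times[i] >= n_bins * dt_ms) continue;
    int j = bin_of(times[i], dt_ms, n_bins);
    out(n, 0) += fw[j] + lc + gain;
    out(n, 1) += f_l1[j] + lc;
    out(n, 2) += lograte_l2 + lc;
    keys[nkeys++] = std::make_pair(n, j);
  }
  keys.resize(nkeys);
  std::sort(keys.begin(), keys.end());
  int run = 1;
  for (size_t i = 1; i <= keys.size(); ++i) {
    if (i < keys.size() && keys[i] == keys[i - 1]) { run++; continue; }
    if (run > 1) {
      double lf = std::lgamma(run + 1.0);
      int n = keys[i - 1].first;
      out(n, 0) -= lf; out(n, 1) -= lf; out(n, 2) -= lf;
    }
    run = 1;
  }
  return out;
}
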