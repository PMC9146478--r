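// Empirical mode decomposition core: extrema detection, mirror-extended
// natural cubic spline envelopes, the sifting loop, and the full EMD driver.
// Kept in C++ because ensemble EMD evaluates the sift thousands of times per
// recording (N noise trials x ~10 IMFs x up to 10 sifts on >20k samples).

#include <Rcpp.h>
using namespace Rcpp;

// Local extrema of x, plateau-aware: a flat run inherits the preceding slope
// sign, so a plateau between a rise and a fall registers one maximum (at the
// last sample of the rise). Indices are 0-based.
static void find_extrema(const NumericVector& x,
                         std::vector<int>& imax, std::vector<int>& imin) {
  const int n = x.size();
  imax.clear(); imin.clear();
  int prev_sign = 0, prev_idx = 0;
  for (int i = 1; i < n; ++i) {
    double d = x[i] - x[i - 1];
    int s = (d > 0) - (d < 0);
    if (s == 0) continue;
    if (prev_sign > 0 && s < 0) imax.push_back(prev_idx);
    else if (prev_sign < 0 && s > 0) imin.push_back(prev_idx);
    prev_sign = s;
    prev_idx = i;
  }
}

static int count_zero_crossings(const NumericVector& x) {
  int prev = 0, cnt = 0;
  for (int i = 0; i < x.size(); ++i) {
    int s = (x[i] > 0) - (x[i] < 0);
    if (s == 0) continue;
    if (prev != 0 && s != prev) ++cnt;
    prev = s;
  }
  return cnt;
}

// Natural cubic spline through (t, y) evaluated at 0..n-1. Linear when only
// two knots. Queries outside the knot range use the end cubic (the mirrored
// knots normally guarantee coverage).
static void natural_spline_eval(const std::vector<double>& t,
                                const std::vector<double>& y,
                                int n, NumericVector& out) {
  const int m = t.size();
  if (m == 2) {
    double slope = (y[1] - y[0]) / (t[1] - t[0]);
    for (int q = 0; q < n; ++q) out[q] = y[0] + slope * (q - t[0]);
    return;
  }
  std::vector<double> h(m - 1), alpha(m, 0.0), l(m), mu(m), z(m), M(m);
  for (int i = 0; i < m - 1; ++i) h[i] = t[i + 1] - t[i];
  for (int i = 1; i < m - 1; ++i)
    alpha[i] = 3.0 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < m - 1; ++i) {
    l[i] = 2.0 * (t[i + 1] - t[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  M[m - 1] = 0.0;
  for (int i = m - 2; i >= 0; --i) M[i] = z[i] - mu[i] * M[i + 1];
  // M[i] here is c_i of the standard natural-spline tridiagonal solve
  // (half the second derivative); evaluate piecewise.
  int seg = 0;
  for (int q = 0; q < n; ++q) {
    double tq = (double) q;
    while (seg < m - 2 && tq > t[seg + 1]) ++seg;
    while (seg > 0 && tq < t[seg]) --seg;
    double hq = h[seg];
    double b = (y[seg + 1] - y[seg]) / hq - hq * (M[seg + 1] + 2.0 * M[seg]) / 3.0;
    double d = (M[seg + 1] - M[seg]) / (3.0 * hq);
    double dx = tq - t[seg];
    out[q] = y[seg] + dx * (b + dx * (M[seg] + dx * d));
  }
}

// Mirror the outermost two extrema of each envelope about the signal ends
// before spline fitting (standard remedy for spline end swings).
static void extend_knots(const std::vector<int>& idx, const NumericVector& x,
                         int n, std::vector<double>& t, std::vector<double>& y) {
  t.clear(); y.clear();
  const int k = idx.size();
  int nmirror = std::min(2, k);
  for (int j = nmirror - 1; j >= 0; --j) {
    double tm = -(double) idx[j];          // reflect about t = 0
    if (tm < -(double) n) continue;
    if (!t.empty() && tm <= t.back()) continue;
    if (tm >= (double) idx[0]) continue;
    t.push_back(tm); y.push_back(x[idx[j]]);
  }
  for (int j = 0; j < k; ++j) { t.push_back((double) idx[j]); y.push_back(x[idx[j]]); }
  for (int j = k - 1; j >= k - nmirror; --j) {
    double tm = 2.0 * (n - 1) - (double) idx[j]; // reflect about t = n-1
    if (tm <= t.back()) continue;
    t.push_back(tm); y.push_back(x[idx[j]]);
  }
}

// Upper/lower envelopes via mirror-extended natural cubic splines through the
// local maxima/minima. ok = false when the signal has fewer than two maxima
// or two minima (monotone / trend condition).
// [[Rcpp::export]]
List cpp_envelopes(NumericVector x) {
  const int n = x.size();
  std::vector<int> imax, imin;
  find_extrema(x, imax, imin);
  if ((int) imax.size() < 2 || (int) imin.size() < 2)
    return List::create(_["ok"] = false,
                        _["n_max"] = (int) imax.size(),
                        _["n_min"] = (int) imin.size());
  NumericVector e_up(n), e_dow(n);
  std::vector<double> t, y;
  extend_knots(imax, x, n, t, y);
  natural_spline_eval(t, y, n, e_up);
  extend_knots(imin, x, n, t, y);
  natural_spline_eval(t, y, n, e_dow);
  return List::create(_["ok"] = true, _["e_up"] = e_up, _["e_dow"] = e_dow,
                      _["n_max"] = (int) imax.size(),
                      _["n_min"] = (int) imin.size());
}

// #extrema, #zero-crossings of x (IMF admissibility bookkeeping).
// [[Rcpp::export]]
IntegerVector cpp_imf_counts(NumericVector x) {
  std::vector<int> imax, imin;
  find_extrema(x, imax, imin);
  return IntegerVector::create(_["n_extrema"] = (int) (imax.size() + imin.size()),
                               _["n_zero"] = count_zero_crossings(x));
}

static bool admissible(const NumericVector& d) {
  std::vector<int> imax, imin;
  find_extrema(d, imax, imin);
  int ne = imax.size() + imin.size();
  return std::abs(ne - count_zero_crossings(d)) <= 1;
}

// One IMF by iterated sifting. Stops when the Cauchy criterion
// SD = sum((d_prev - d_cur)^2) / sum(d_prev^2) drops below sd_tol and the
// candidate passes the extrema/zero-crossing condition, or at max_sift.
// [[Rcpp::export]]
List cpp_extract_imf(NumericVector x, double sd_tol, int max_sift) {
  const int n = x.size();
  NumericVector d = clone(x);
  int it = 0;
  bool converged = false, siftable = false;
  std::vector<int> imax, imin;
  std::vector<double> t, y;
  NumericVector e_up(n), e_dow(n);
  while (it < max_sift) {
    find_extrema(d, imax, imin);
    if ((int) imax.size() < 2 || (int) imin.size() < 2) break;
    siftable = true;
    extend_knots(imax, d, n, t, y);
    natural_spline_eval(t, y, n, e_up);
    extend_knots(imin, d, n, t, y);
    natural_spline_eval(t, y, n, e_dow);
    double num = 0.0, den = 0.0;
    for (int i = 0; i < n; ++i) {
      double m = 0.5 * (e_up[i] + e_dow[i]);
      num += m * m;
      den += d[i] * d[i];
      d[i] -= m;
    }
    ++it;
    if (den > 0.0 && num / den < sd_tol && admissible(d)) { converged = true; break; }
  }
  return List::create(_["imf"] = d, _["n_sift"] = it,
                      _["converged"] = converged, _["siftable"] = siftable);
}

// Full EMD: peel IMFs until the remainder is monotone/trend-like or max_imf
// is reached. Residual = input - sum(IMFs) exactly (telescoping).
// [[Rcpp::export]]
List cpp_emd(NumericVector x, double sd_tol, int max_sift, int max_imf) {
  const int n = x.size();
  std::vector<NumericVector> imfs;
  NumericVector r = clone(x);
  for (int k = 0; k < max_imf; ++k) {
    List res = cpp_extract_imf(r, sd_tol, max_sift);
    if (!as<bool>(res["siftable"])) break;
    NumericVector imf = res["imf"];
    for (int i = 0; i < n; ++i) r[i] -= imf[i];
    imfs.push_back(imf);
  }
  NumericMatrix M(n, (int) imfs.size());
  for (int k = 0; k < (int) imfs.size(); ++k)
    for (int i = 0; i < n; ++i) M(i, k) = imfs[k][i];
  return List::create(_["imfs"] = M, _["residual"] = r);
}
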