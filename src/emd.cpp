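// Empirical mode decomposition: sifting with cubic-spline envelopes.
// Envelopes interpolate local extrema, mirror-extended by two extrema at
// each boundary; sifting stops on a Cauchy criterion or an iteration cap.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Local maxima/minima of x as 0-based indices. A plateau contributes its
// midpoint. Endpoints are never extrema (they enter via mirror extension).
static void local_extrema(const std::vector<double>& x,
                          std::vector<int>& maxima,
                          std::vector<int>& minima) {
  maxima.clear();
  minima.clear();
  const int n = static_cast<int>(x.size());
  int i = 1;
  while (i < n - 1) {
    double dl = x[i] - x[i - 1];
    if (dl == 0.0) { ++i; continue; }
    // advance over a plateau to its right edge
    int j = i;
    while (j < n - 1 && x[j + 1] == x[j]) ++j;
    if (j >= n - 1) break;
    double dr = x[j + 1] - x[j];
    int mid = (i + j) / 2;
    if (dl > 0.0 && dr < 0.0) maxima.push_back(mid);
    else if (dl < 0.0 && dr > 0.0) minima.push_back(mid);
    i = j + 1;
  }
}

// Natural cubic spline through (t, v), evaluated at 0..n-1.
static std::vector<double> spline_eval(const std::vector<double>& t,
                                       const std::vector<double>& v,
                                       int n) {
  const int m = static_cast<int>(t.size());
  std::vector<double> out(n);
  if (m == 1) {
    std::fill(out.begin(), out.end(), v[0]);
    return out;
  }
  if (m == 2) {
    double slope = (v[1] - v[0]) / (t[1] - t[0]);
    for (int i = 0; i < n; ++i) out[i] = v[0] + slope * (i - t[0]);
    return out;
  }
  // second derivatives by tridiagonal solve (natural boundary conditions)
  std::vector<double> h(m - 1), alpha(m, 0.0), l(m), mu(m), z(m), c(m);
  for (int i = 0; i < m - 1; ++i) h[i] = t[i + 1] - t[i];
  for (int i = 1; i < m - 1; ++i)
    alpha[i] = 3.0 * ((v[i + 1] - v[i]) / h[i] - (v[i] - v[i - 1]) / h[i - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < m - 1; ++i) {
    l[i] = 2.0 * (t[i + 1] - t[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  c[m - 1] = 0.0;
  for (int i = m - 2; i >= 0; --i) c[i] = z[i] - mu[i] * c[i + 1];

  int seg = 0;
  for (int i = 0; i < n; ++i) {
    double xi = static_cast<double>(i);
    while (seg < m - 2 && t[seg + 1] < xi) ++seg;
    double dt = xi - t[seg], hh = h[seg];
    double b = (v[seg + 1] - v[seg]) / hh - hh * (c[seg + 1] + 2.0 * c[seg]) / 3.0;
    double d = (c[seg + 1] - c[seg]) / (3.0 * hh);
    out[i] = v[seg] + b * dt + c[seg] * dt * dt + d * dt * dt * dt;
  }
  return out;
}

// Envelope through extrema `idx` of x, with `next_ext` mirror points per side.
static std::vector<double> envelope(const std::vector<double>& x,
                                    const std::vector<int>& idx,
                                    int next_ext = 2) {
  const int n = static_cast<int>(x.size());
  const int k = static_cast<int>(idx.size());
  std::vector<double> t, v;
  t.reserve(k + 2 * next_ext);
  v.reserve(k + 2 * next_ext);
  int nl = std::min(next_ext, k);
  // mirror about the first sample: t -> -t
  for (int i = nl - 1; i >= 0; --i) {
    t.push_back(-static_cast<double>(idx[i]));
    v.push_back(x[idx[i]]);
  }
  for (int i = 0; i < k; ++i) {
    t.push_back(static_cast<double>(idx[i]));
    v.push_back(x[idx[i]]);
  }
  // mirror about the last sample: t -> 2(n-1) - t
  for (int i = 0; i < nl; ++i) {
    int j = k - 1 - i;
    t.push_back(2.0 * (n - 1) - static_cast<double>(idx[j]));
    v.push_back(x[idx[j]]);
  }
  // mirrored points can coincide when an extremum sits on the boundary
  std::vector<double> tt, vv;
  for (size_t i = 0; i < t.size(); ++i) {
    if (tt.empty() || t[i] > tt.back()) { tt.push_back(t[i]); vv.push_back(v[i]); }
  }
  return spline_eval(tt, vv, n);
}

// Mean of upper and lower envelopes; writable only when each envelope has
// at least two support points. Returns false otherwise.
static bool envelope_mean(const std::vector<double>& x, std::vector<double>& m) {
  std::vector<int> maxima, minima;
  local_extrema(x, maxima, minima);
  if (maxima.size() < 2 || minima.size() < 2) return false;
  std::vector<double> up = envelope(x, maxima);
  std::vector<double> lo = envelope(x, minima);
  m.resize(x.size());
  for (size_t i = 0; i < x.size(); ++i) m[i] = 0.5 * (up[i] + lo[i]);
  return true;
}

// [[Rcpp::export(name = ".envelope_mean_cpp")]]
Rcpp::List envelope_mean_cpp(NumericVector x) {
  std::vector<double> xv(x.begin(), x.end()), m;
  bool ok = envelope_mean(xv, m);
  if (!ok) return List::create(_["ok"] = false, _["mean"] = R_NilValue);
  return List::create(_["ok"] = true, _["mean"] = NumericVector(m.begin(), m.end()));
}

// [[Rcpp::export(name = ".extrema_cpp")]]
Rcpp::List extrema_cpp(NumericVector x) {
  std::vector<double> xv(x.begin(), x.end());
  std::vector<int> maxima, minima;
  local_extrema(xv, maxima, minima);
  IntegerVector mx(maxima.begin(), maxima.end()), mn(minima.begin(), minima.end());
  return List::create(_["maxima"] = mx + 1, _["minima"] = mn + 1);  // 1-based
}

// Zero crossings, ignoring exact zeros.
static int zero_crossings(const std::vector<double>& x) {
  int count = 0;
  double prev = 0.0;
  for (size_t i = 0; i < x.size(); ++i) {
    if (x[i] == 0.0) continue;
    if (prev != 0.0 && ((x[i] > 0.0) != (prev > 0.0))) ++count;
    prev = x[i];
  }
  return count;
}

// IMF count requirement: local extrema and zero crossings differ <= 1.
static bool count_rule(const std::vector<double>& x) {
  std::vector<int> maxima, minima;
  local_extrema(x, maxima, minima);
  int ne = static_cast<int>(maxima.size() + minima.size());
  return std::abs(ne - zero_crossings(x)) <= 1;
}

// One sifting pass sequence: iterate y <- y - m(y) until the IMF count
// requirement holds together with the Cauchy criterion
// sum(m^2)/sum(y^2) < sd_tol, or max_iter passes have run. Empty vector
// when no IMF is extractable (fewer than two maxima or two minima).
static std::vector<double> sift(const std::vector<double>& x,
                                double sd_tol, int max_iter) {
  std::vector<double> y(x), m;
  if (!envelope_mean(y, m)) return std::vector<double>();
  for (int it = 0; it < max_iter; ++it) {
    double num = 0.0, den = 0.0;
    for (size_t i = 0; i < y.size(); ++i) {
      num += m[i] * m[i];
      den += y[i] * y[i];
      y[i] -= m[i];
    }
    if ((den <= 0.0 || num / den < sd_tol) && count_rule(y)) break;
    if (!envelope_mean(y, m)) break;
  }
  return y;
}

// [[Rcpp::export(name = ".sift_cpp")]]
Rcpp::NumericVector sift_cpp(NumericVector x, double sd_tol, int max_iter) {
  std::vector<double> xv(x.begin(), x.end());
  std::vector<double> y = sift(xv, sd_tol, max_iter);
  if (y.empty()) stop("no IMF extractable: fewer than two maxima or two minima");
  return NumericVector(y.begin(), y.end());
}

// [[Rcpp::export(name = ".emd_cpp")]]
Rcpp::List emd_cpp(NumericVector x, int max_modes, double sd_tol, int max_iter) {
  const int n = x.size();
  std::vector<double> r(x.begin(), x.end());
  std::vector<std::vector<double> > imfs;
  std::vector<int> maxima, minima;
  for (int mode = 0; mode < max_modes; ++mode) {
    local_extrema(r, maxima, minima);
    if (static_cast<int>(maxima.size() + minima.size()) < 2) break;  // monotone-ish residual
    std::vector<double> imf = sift(r, sd_tol, max_iter);
    if (imf.empty()) break;
    double energy = 0.0;
    for (int i = 0; i < n; ++i) energy += imf[i] * imf[i];
    if (energy == 0.0) break;
    for (int i = 0; i < n; ++i) r[i] -= imf[i];
    imfs.push_back(imf);
  }
  NumericMatrix im(n, static_cast<int>(imfs.size()));
  for (size_t j = 0; j < imfs.size(); ++j)
    for (int i = 0; i < n; ++i) im(i, static_cast<int>(j)) = imfs[j][i];
  return List::create(_["imfs"] = im,
                      _["residual"] = NumericVector(r.begin(), r.end()));
}
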