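#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Beat-by-beat RR generation. The next interval is evaluated at the current
// cumulative time, then time advances by that interval (so the RRSeries
// invariant t[i+1] - t[i] == rr[i+1]/1000 holds by construction). Noise is
// drawn through R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
List gen_rr_cpp(double mesor, double circ_amp, double acro_h,
                double hf_amp, double hf_freq, double lf_amp, double lf_freq,
                double band_gain, double band_acro_h,
                double noise_sd, double duration_s) {
  const double day = 86400.0, two_pi = 2.0 * M_PI;
  std::vector<double> t, rr;
  size_t guess = (size_t)(duration_s / (mesor / 1000.0) * 1.2) + 16;
  t.reserve(guess); rr.reserve(guess);
  double cur = 0.0;
  while (true) {
    double circ = circ_amp * std::cos(two_pi * (cur - acro_h * 3600.0) / day);
    double gain = 1.0 + band_gain * std::cos(two_pi * (cur - band_acro_h * 3600.0) / day);
    double x = mesor + circ
      + hf_amp * gain * std::sin(two_pi * hf_freq * cur)
      + lf_amp * gain * std::sin(two_pi * lf_freq * cur);
    if (noise_sd > 0.0) x += R::rnorm(0.0, noise_sd);
    if (x <= 0.0) x = 1.0;  // guarded by the spec invariant; belt and braces
    cur += x / 1000.0;
    rr.push_back(x);
    t.push_back(cur);
    if (cur >= duration_s) break;
  }
  // shift so the first beat sits at t = 0
  double t0 = t.empty() ? 0.0 : t[0];
  for (size_t i = 0; i < t.size(); ++i) t[i] -= t0;
  return List::create(_["t"] = wrap(t), _["rr"] = wrap(rr));
}

static double median_of(std::vector<double> &v) {
  size_t n = v.size(), h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    std::nth_element(v.begin(), v.begin() + h - 1, v.begin() + h);
    m = 0.5 * (m + v[h - 1]);
  }
  return m;
}

// Threshold artifact detection: beat i is flagged when its relative deviation
// from the median of the k nearest (by index) not-yet-flagged neighbours
// exceeds `threshold`. Sequential left-to-right pass; deterministic.
// [[Rcpp::export]]
LogicalVector detect_artifacts_cpp(NumericVector rr, double threshold, int k) {
  int n = rr.size();
  LogicalVector flag(n, false);
  std::vector<double> nb; nb.reserve(k);
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int d = 1; (int)nb.size() < k && d < n; ++d) {
      int lo = i - d, hi = i + d;
      if (lo >= 0 && !flag[lo]) nb.push_back(rr[lo]);
      if ((int)nb.size() < k && hi < n && !flag[hi]) nb.push_back(rr[hi]);
      if (lo < 0 && hi >= n) break;
    }
    if (nb.empty()) continue;
    double m = median_of(nb);
    if (m > 0 && std::abs(rr[i] - m) / m > threshold) flag[i] = true;
  }
  return flag;
}

// Template-match counts for ApEn/SampEn (Chebyshev distance).
// Returns, for template length m:
//   phi_m, phi_m1: ApEn sums (self-matches included, log of C_i averaged)
//   A, B: SampEn pair counts at m+1 and m (self-matches excluded)
// [[Rcpp::export]]
List entropy_counts_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  int Nm = n - m;  // template count shared by lengths m and m+1 (SampEn)
  // ApEn convention: N - m + 1 templates of length m
  int Am = n - m + 1, Am1 = n - m;
  double phi_m = 0.0, phi_m1 = 0.0;
  // ApEn length-m templates
  for (int i = 0; i < Am; ++i) {
    int c = 0;
    for (int j = 0; j < Am; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k)
        d = std::max(d, std::abs(x[i + k] - x[j + k]));
      if (d <= r) ++c;
    }
    phi_m += std::log((double)c / Am);
  }
  phi_m /= Am;
  for (int i = 0; i < Am1; ++i) {
    int c = 0;
    for (int j = 0; j < Am1; ++j) {
      double d = 0.0;
      for (int k = 0; k <= m; ++k)
        d = std::max(d, std::abs(x[i + k] - x[j + k]));
      if (d <= r) ++c;
    }
    phi_m1 += std::log((double)c / Am1);
  }
  phi_m1 /= Am1;
  // SampEn: pairs i < j among the n - m templates (standard convention:
  // both template sets have length n - m so A/B is a ratio of probabilities)
  double A = 0.0, B = 0.0;
  for (int i = 0; i < Nm; ++i) {
    for (int j = i + 1; j < Nm; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k)
        d = std::max(d, std::abs(x[i + k] - x[j + k]));
      if (d <= r) {
        B += 1.0;
        double d1 = std::max(d, std::abs(x[i + m] - x[j + m]));
        if (d1 <= r) A += 1.0;
      }
    }
  }
  return List::create(_["phi_m"] = phi_m, _["phi_m1"] = phi_m1,
                      _["A"] = A, _["B"] = B);
}

// Correlation sums C(r_g) for Grassberger-Procaccia on a delay embedding.
// emb: N x m matrix of embedded vectors; rgrid ascending.
// [[Rcpp::export]]
NumericVector corr_sums_cpp(NumericMatrix emb, NumericVector rgrid) {
  int N = emb.nrow(), m = emb.ncol(), G = rgrid.size();
  std::vector<double> cnt(G, 0.0);
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double s = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = emb(i, k) - emb(j, k);
        s += d * d;
      }
      double dist = std::sqrt(s);
      // count into all grid radii >= dist (grid ascending)
      int lo = std::lower_bound(rgrid.begin(), rgrid.end(), dist) - rgrid.begin();
      for (int g = lo; g < G; ++g) cnt[g] += 1.0;
    }
  }
  NumericVector out(G);
  double denom = 0.5 * (double)N * (N - 1);
  for (int g = 0; g < G; ++g) out[g] = cnt[g] / denom;
  return out;
}

// Recurrence quantification on a delay embedding: recurrence rate and
// determinism (share of recurrent points on diagonal lines of length >= lmin).
// Euclidean norm, i != j.
// [[Rcpp::export]]
List rqa_cpp(NumericMatrix emb, double r, int lmin) {
  int N = emb.nrow(), m = emb.ncol();
  double total = 0.0, on_lines = 0.0;
  double r2 = r * r;
  // scan upper-triangle diagonals; matrix is symmetric so double the counts
  for (int d = 1; d < N; ++d) {
    int len = N - d, run = 0;
    for (int i = 0; i < len; ++i) {
      double s = 0.0;
      for (int k = 0; k < m; ++k) {
        double v = emb(i, k) - emb(i + d, k);
        s += v * v;
      }
      bool rec = (s <= r2);
      if (rec) { total += 1.0; ++run; }
      if (!rec || i == len - 1) {
        if (run >= lmin) on_lines += run;
        run = 0;
      }
    }
  }
  double denom = (double)N * (N - 1);
  double recp = 100.0 * (2.0 * total) / denom;
  double detp = total > 0 ? 100.0 * on_lines / total : NA_REAL;
  return List::create(_["rec"] = recp, _["det"] = detp,
                      _["n_recurrent"] = 2.0 * total);
}
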