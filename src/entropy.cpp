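#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Template-matching aggregates for approximate and sample entropy in one
// sweep. Distances are Chebyshev over embedded vectors of length m and m+1.
// ApEn counts matches with d <= r and includes the self-match; SampEn counts
// d < r and excludes self-matches (see the R-level documentation for the
// exact normalisations). Pairs are enumerated through a sliding window over
// the series sorted by first template coordinate: any pair whose first
// coordinates differ by more than r cannot match at either dimension, so
// only near pairs are examined in full.
// [[Rcpp::export]]
List apen_sampen_aggregates(NumericVector x, int m, double r) {
  const int N = x.size();
  const int nm = N - m + 1;   // templates of length m
  const int nm1 = N - m;      // templates of length m+1
  if (nm1 < 2) stop("series too short for embedding dimension m=%d", m);

  std::vector<double> cA(nm, 0.0), cA1(nm1, 0.0);
  std::vector<double> cS(nm, 0.0), cS1(nm1, 0.0);

  std::vector<int> ord(nm);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });

  for (int a = 0; a < nm - 1; ++a) {
    const int i = ord[a];
    for (int bidx = a + 1; bidx < nm; ++bidx) {
      const int j = ord[bidx];
      if (x[j] - x[i] > r) break;   // sorted: no later pair can match
      double dm = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(x[i + k] - x[j + k]);
        if (d > dm) dm = d;
        if (dm > r) break;
      }
      if (dm > r) continue;
      if (dm <= r) { cA[i] += 1; cA[j] += 1; }
      if (dm < r)  { cS[i] += 1; cS[j] += 1; }
      if (i < nm1 && j < nm1) {
        double d = std::fabs(x[i + m] - x[j + m]);
        double dm1 = (d > dm) ? d : dm;
        if (dm1 <= r) { cA1[i] += 1; cA1[j] += 1; }
        if (dm1 < r)  { cS1[i] += 1; cS1[j] += 1; }
      }
    }
  }

  // ApEn: self-match included, c_i(m,r) = c_i / n_templates, phi = mean(ln c)
  double phi_m = 0.0, phi_m1 = 0.0;
  for (int i = 0; i < nm; ++i)  phi_m  += std::log((cA[i] + 1.0) / nm);
  for (int i = 0; i < nm1; ++i) phi_m1 += std::log((cA1[i] + 1.0) / nm1);
  phi_m /= nm;
  phi_m1 /= nm1;

  // SampEn: B_i^m = matches/(N-m), averaged over the N-m+1 templates;
  // at dimension m+1 the analogous normalisations with m -> m+1.
  double Bm = 0.0, Bm1 = 0.0;
  for (int i = 0; i < nm; ++i)  Bm  += cS[i] / (double)(N - m);
  for (int i = 0; i < nm1; ++i) Bm1 += cS1[i] / (double)(N - m - 1);
  Bm /= nm;
  Bm1 /= nm1;

  return List::create(_["phi_m"] = phi_m, _["phi_m1"] = phi_m1,
                      _["B_m"] = Bm, _["B_m1"] = Bm1);
}

// Gaussian similarity with the exponent clamped: arguments beyond 46 give
// exp(-46) < 1e-20, far below any tolerance used here, and skipping them
// avoids subnormal slow paths.
static inline double gauss_sim(double d, double nexp, double r) {
  double a = (nexp == 2.0) ? d * d / r
           : (nexp == 1.0) ? d / r
           : std::pow(d, nexp) / r;
  return (a > 46.0) ? 0.0 : std::exp(-a);
}

// Fuzzy-entropy aggregates Phi^m and Phi^{m+1}: mean-removed templates,
// Chebyshev distance, Gaussian similarity D = exp(-d^n / r).
// [[Rcpp::export]]
List fuzzyen_aggregates(NumericVector x, int m, double r, double nexp) {
  const int N = x.size();
  const int nm = N - m + 1;
  const int nm1 = N - m;
  if (nm1 < 2) stop("series too short for embedding dimension m=%d", m);

  // rolling template means at lengths m and m+1
  std::vector<double> mu(nm), mu1(nm1);
  double s = 0.0;
  for (int k = 0; k < m; ++k) s += x[k];
  for (int i = 0; i < nm; ++i) {
    mu[i] = s / m;
    if (i + m < N) s += x[i + m] - x[i];
  }
  s = 0.0;
  for (int k = 0; k < m + 1; ++k) s += x[k];
  for (int i = 0; i < nm1; ++i) {
    mu1[i] = s / (m + 1);
    if (i + m + 1 < N) s += x[i + m + 1] - x[i];
  }

  double sum_m = 0.0, sum_m1 = 0.0;
  for (int i = 0; i < nm - 1; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      double off = mu[i] - mu[j], dm = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(x[i + k] - x[j + k] - off);
        if (d > dm) dm = d;
      }
      sum_m += 2.0 * gauss_sim(dm, nexp, r);
      if (i < nm1 && j < nm1) {
        double off1 = mu1[i] - mu1[j], dm1 = 0.0;
        for (int k = 0; k < m + 1; ++k) {
          double d = std::fabs(x[i + k] - x[j + k] - off1);
          if (d > dm1) dm1 = d;
        }
        sum_m1 += 2.0 * gauss_sim(dm1, nexp, r);
      }
    }
  }
  double Phi_m = sum_m / ((double)nm * (N - m));
  double Phi_m1 = sum_m1 / ((double)nm1 * (N - m - 1));
  return List::create(_["Phi_m"] = Phi_m, _["Phi_m1"] = Phi_m1);
}

// Higuchi curve lengths L(k), k = 1..kmax.
// [[Rcpp::export]]
NumericVector higuchi_curve_cpp(NumericVector x, int kmax) {
  const int N = x.size();
  NumericVector L(kmax);
  for (int k = 1; k <= kmax; ++k) {
    double Lk = 0.0;
    int nvalid = 0;
    for (int m0 = 0; m0 < k; ++m0) {
      const int M = (N - 1 - m0) / k;   // segments in this subseries
      if (M < 1) continue;
      double sum = 0.0;
      for (int i = 1; i <= M; ++i) {
        sum += std::fabs(x[m0 + i * k] - x[m0 + (i - 1) * k]);
      }
      Lk += sum * (double)(N - 1) / ((double)M * k) / k;
      ++nvalid;
    }
    L[k - 1] = (nvalid > 0) ? Lk / nvalid : NA_REAL;
  }
  return L;
}
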