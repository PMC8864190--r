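#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Exhaustive circular-arc scan for one chromosome of bin ratios.
// Arcs are (i, j] in 0-based cumulative-sum coordinates, 0 <= i < j <= n;
// the arc and its complement must both hold at least min_width bins.
// Wrapping arcs are complements of scanned arcs and |t| is symmetric, so
// scanning non-wrapping arcs covers the full circle.  The statistic is the
// pooled-variance two-sample t between in-arc and out-of-arc bins, with a
// variance floor of 1e-8 for degenerate (constant) data.  Ties in the argmax
// are broken toward the smallest i, then the smallest j (scan order, strict
// improvement).  Internally the comparison works on t^2 via cross-
// multiplication so the hot loop has no division or square root.
// If stop_at > 0, the scan returns as soon as any arc reaches it (used
// inside the permutation loop, where only exceedance matters).
static double max_t_scan(const std::vector<double> &x, int min_width,
                         const std::vector<double> &w, int *bi, int *bj,
                         double stop_at) {
  const int n = (int)x.size();
  *bi = -1;
  *bj = -1;
  if (n < 2 * min_width) return -1.0;
  std::vector<double> S(n + 1, 0.0);
  double ssq = 0.0;
  for (int t = 0; t < n; ++t) {
    S[t + 1] = S[t] + x[t];
    ssq += x[t] * x[t];
  }
  const double total = S[n];
  const double inv_df = 1.0 / ((n > 2) ? (double)(n - 2) : 1.0);
  const double stop2 = (stop_at > 0) ? stop_at * stop_at : -1.0;
  double best2 = 0.0; // best t^2 so far
  int besti = -1, bestj = -1;
  for (int i = 0; i <= n - min_width; ++i) {
    const int jmax = std::min(n, i + (n - min_width));
    const double Si = S[i];
    for (int j = i + min_width; j <= jmax; ++j) {
      const int k = j - i;
      const int m = n - k;
      const double sumA = S[j] - Si;
      const double mA = sumA / k;
      const double mB = (total - sumA) / m;
      double var = (ssq - (double)k * mA * mA - (double)m * mB * mB) * inv_df;
      if (var < 1e-8) var = 1e-8;
      const double diff = mA - mB;
      const double num = diff * diff;
      const double scale = var * w[k]; // w[k] = 1/k + 1/(n-k)
      // t^2 = num / scale; avoid the division unless it improves
      if (num > best2 * scale * (1.0 + 1e-12)) {
        best2 = num / scale;
        besti = i;
        bestj = j;
        if (stop2 > 0 && best2 >= stop2) {
          *bi = besti;
          *bj = bestj;
          return std::sqrt(best2);
        }
      }
    }
  }
  *bi = besti;
  *bj = bestj;
  return (besti < 0) ? -1.0 : std::sqrt(best2);
}

static std::vector<double> width_weights(int n) {
  std::vector<double> w(n + 1, 0.0);
  for (int k = 1; k < n; ++k) w[k] = 1.0 / k + 1.0 / (n - k);
  return w;
}

// [[Rcpp::export]]
List cpp_cbs_scan(NumericVector x, int min_width) {
  std::vector<double> v(x.begin(), x.end());
  std::vector<double> w = width_weights(v.size());
  int bi, bj;
  double t = max_t_scan(v, min_width, w, &bi, &bj, -1.0);
  return List::create(_["tmax"] = t, _["i"] = bi, _["j"] = bj);
}

// Permutation p-value of the observed max-|t| under full within-chromosome
// shuffles, with sequential early stopping in both directions: once the
// exceedance count guarantees p > alpha the loop aborts (rejection), and
// when no permutation has exceeded the observed statistic after
// `early_accept` shuffles the split is accepted without running the rest
// (curtailed p-value 0).  Uses R's RNG, so results are reproducible under
// set.seed().
// [[Rcpp::export]]
double cpp_cbs_perm_p(NumericVector x, double tobs, int min_width, int nperm,
                      double alpha, int early_accept) {
  const int n = x.size();
  std::vector<double> v(x.begin(), x.end());
  std::vector<double> w = width_weights(n);
  const int maxexc = (int)std::floor(alpha * nperm);
  int exc = 0;
  int bi, bj;
  for (int p = 1; p <= nperm; ++p) {
    for (int t = n - 1; t > 0; --t) {
      int u = (int)(unif_rand() * (t + 1));
      if (u > t) u = t;
      std::swap(v[t], v[u]);
    }
    const double tp = max_t_scan(v, min_width, w, &bi, &bj, tobs - 1e-12);
    if (tp >= tobs - 1e-12) {
      ++exc;
      if (exc > maxexc) return (double)exc / (double)p;
    }
    if (p == early_accept && exc == 0) return 0.0;
  }
  return (double)exc / (double)nperm;
}
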