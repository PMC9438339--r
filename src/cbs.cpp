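// Circular binary segmentation split test.
//
// For a segment x[0..n-1] viewed as a circle, every arc (i, j] (0 <= i <
// j <= n, arc and complement each at least min_width bins) is scored by
// the two-sample t-like statistic comparing the arc mean with the
// complement mean under the segment-wide variance.  The maximal |T| is
// compared against permutations of x; early stopping abandons the
// permutation loop as soon as significance can no longer be reached.
// Uses R's RNG so results are reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// maximal |T| over arcs; returns best arc via bi/bj (arc = x[bi..bj-1],
// 0-based), or tmax = -1 when the segment is constant.
static double max_arc_t(const std::vector<double>& x, int min_w,
                        int* bi, int* bj) {
  const int n = (int)x.size();
  std::vector<double> cs(n + 1, 0.0);
  for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + x[i];
  const double total = cs[n];
  const double mean = total / n;
  double ss = 0.0;
  for (int i = 0; i < n; ++i) ss += (x[i] - mean) * (x[i] - mean);
  if (ss <= 0.0) { *bi = -1; *bj = -1; return -1.0; }
  const double s = std::sqrt(ss / (n - 1));
  double tmax = -1.0;
  *bi = -1; *bj = -1;
  for (int i = 0; i + min_w <= n; ++i) {
    const int jmax = std::min(n, i + (n - min_w));
    for (int j = i + min_w; j <= jmax; ++j) {
      const int k = j - i;
      if (n - k < min_w) continue;
      const double m_arc = (cs[j] - cs[i]) / k;
      const double m_comp = (total - (cs[j] - cs[i])) / (n - k);
      const double t = std::fabs(m_arc - m_comp) /
        (s * std::sqrt(1.0 / k + 1.0 / (n - k)));
      if (t > tmax) { tmax = t; *bi = i; *bj = j; }
    }
  }
  return tmax;
}

// [[Rcpp::export]]
List cbs_split(NumericVector xr, double alpha, int n_perm, int min_width) {
  const int n = xr.size();
  std::vector<double> x(xr.begin(), xr.end());
  int bi, bj;
  const double t_obs = max_arc_t(x, min_width, &bi, &bj);
  if (t_obs < 0.0 || bi < 0) {
    return List::create(_["significant"] = false, _["i"] = NA_INTEGER,
                        _["j"] = NA_INTEGER, _["p"] = 1.0);
  }
  // significance requires exceed < alpha * n_perm at the end; abandon as
  // soon as that is impossible.
  const double cutoff = alpha * n_perm;
  int exceed = 0, done = 0;
  std::vector<double> perm(x);
  RNGScope scope;
  for (int p = 0; p < n_perm; ++p) {
    for (int k = n - 1; k > 0; --k) {
      int idx = (int)(unif_rand() * (k + 1));
      if (idx > k) idx = k;
      std::swap(perm[k], perm[idx]);
    }
    int a, b;
    const double t = max_arc_t(perm, min_width, &a, &b);
    if (t >= t_obs) ++exceed;
    ++done;
    if ((double)exceed >= cutoff) break;
  }
  const bool significant = (done == n_perm) && ((double)exceed < cutoff);
  return List::create(_["significant"] = significant,
                      _["i"] = bi, _["j"] = bj,
                      _["p"] = (double)exceed / (double)done);
}
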