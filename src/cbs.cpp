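#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Maximum arc statistic for circular binary segmentation.
// For a sequence x of length n, scan all arcs [i, j) (0-based half-open,
// 1 <= j - i < n) and score the contrast between the arc mean and the mean of
// the complement under a common-variance model:
//   z(i, j) = |S(i,j) - (m/n) S| / sqrt(m (n - m) / n),  m = j - i.
// Ties are broken by the lexicographically earliest (i, j).
static void max_arc(const std::vector<double> &cs, int n,
                    int &bi, int &bj, double &best) {
  const double total = cs[n];
  best = -1.0; bi = 0; bj = n;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j <= n; ++j) {
      int m = j - i;
      if (m == n) continue;
      double s = cs[j] - cs[i];
      double mu = (double)m / n * total;
      double z = std::fabs(s - mu) / std::sqrt((double)m * (n - m) / n);
      if (z > best) { best = z; bi = i; bj = j; }
    }
  }
}

// [[Rcpp::export(name = ".cbs_max_arc")]]
List cbs_max_arc(NumericVector x) {
  int n = x.size();
  std::vector<double> cs(n + 1, 0.0);
  for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + x[i];
  int bi, bj; double best;
  max_arc(cs, n, bi, bj, best);
  return List::create(_["i"] = bi, _["j"] = bj, _["stat"] = best);
}

// Permutation p-value for the observed max arc statistic, with early
// termination: once the exceedance count makes p > alpha certain, stop.
// Returns the add-one p estimate (upper-biased when stopped early, which is
// harmless because the split is rejected either way). Uses R's RNG.
// [[Rcpp::export(name = ".cbs_perm_pvalue")]]
double cbs_perm_pvalue(NumericVector x, double observed, int n_perm,
                       double alpha) {
  int n = x.size();
  std::vector<double> perm(x.begin(), x.end());
  std::vector<double> cs(n + 1, 0.0);
  int max_exceed = (int)std::floor(alpha * (n_perm + 1.0)) - 1;
  int exceed = 0, done = 0;
  RNGScope scope;
  for (int b = 0; b < n_perm; ++b) {
    // Fisher-Yates shuffle
    for (int k = n - 1; k > 0; --k) {
      int idx = (int)(unif_rand() * (k + 1));
      if (idx > k) idx = k;
      std::swap(perm[k], perm[idx]);
    }
    for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + perm[i];
    int bi, bj; double best;
    max_arc(cs, n, bi, bj, best);
    ++done;
    if (best >= observed) {
      ++exceed;
      if (exceed > max_exceed) break;  // cannot reach p <= alpha any more
    }
  }
  return (1.0 + exceed) / (1.0 + (exceed > max_exceed ? done : n_perm));
}
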