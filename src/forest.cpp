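// Random forest for binary classification, used only for its Gini
// importance: at every split the decrease in (size-weighted) Gini impurity
// is credited to the splitting feature; importances are summed per tree and
// averaged over trees -- the usual mean-decrease-in-Gini measure.

#include <Rcpp.h>
#include <random>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Forest {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry;
  std::mt19937 rng;
  std::vector<double> importance;

  Forest(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
         unsigned seed)
      : X(X_), y(y_), mtry(mtry_), rng(seed),
        importance(X_.ncol(), 0.0) {}

  static double gini(int n1, int n) {
    if (n == 0) return 0.0;
    double p = (double)n1 / n;
    return 2.0 * p * (1.0 - p);
  }

  void grow(std::vector<int>& idx, int lo, int hi, int depth) {
    int n = hi - lo;
    if (n < 2 || depth > 30) return;
    int n1 = 0;
    for (int t = lo; t < hi; ++t) n1 += y[idx[t]];
    if (n1 == 0 || n1 == n) return;

    // sample mtry candidate features without replacement
    int p = X.ncol();
    std::vector<int> feats(p);
    for (int c = 0; c < p; ++c) feats[c] = c;
    for (int c = 0; c < mtry; ++c) {
      int r = c + (int)(rng() % (unsigned)(p - c));
      std::swap(feats[c], feats[r]);
    }

    double parent = gini(n1, n) * n;
    double best_dec = 1e-12;
    int best_feat = -1;
    double best_thr = 0.0;
    std::vector<int> node(idx.begin() + lo, idx.begin() + hi);
    for (int c = 0; c < mtry; ++c) {
      int feat = feats[c];
      std::sort(node.begin(), node.end(), [&](int a, int b) {
        return X(a, feat) < X(b, feat);
      });
      int left1 = 0;
      for (int t = 0; t < n - 1; ++t) {
        left1 += y[node[t]];
        if (X(node[t], feat) == X(node[t + 1], feat)) continue;
        int nl = t + 1, nr = n - nl;
        double dec = parent - gini(left1, nl) * nl - gini(n1 - left1, nr) * nr;
        if (dec > best_dec) {
          best_dec = dec;
          best_feat = feat;
          best_thr = 0.5 * (X(node[t], feat) + X(node[t + 1], feat));
        }
      }
    }
    if (best_feat < 0) return;
    importance[best_feat] += best_dec;

    // partition in place
    int mid = lo;
    for (int t = lo; t < hi; ++t)
      if (X(idx[t], best_feat) <= best_thr) std::swap(idx[t], idx[mid++]);
    grow(idx, lo, mid, depth + 1);
    grow(idx, mid, hi, depth + 1);
  }
};

}  // namespace

// [[Rcpp::export]]
NumericVector rf_gini_importance(NumericMatrix X, IntegerVector y, int ntree,
                                 int mtry, int seed) {
  const int n = X.nrow();
  Forest forest(X, y, mtry, (unsigned)seed);
  std::vector<int> idx(n);
  for (int t = 0; t < ntree; ++t) {
    for (int i = 0; i < n; ++i)
      idx[i] = (int)(forest.rng() % (unsigned)n);  // bootstrap sample
    forest.grow(idx, 0, n, 0);
  }
  NumericVector out(X.ncol());
  for (int c = 0; c < X.ncol(); ++c) out[c] = forest.importance[c] / ntree;
  return out;
}
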