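// RBF-kernel support vector machine trained with the simplified SMO
// algorithm. Small dense problems only (pair feature vectors are a handful
// of similarity values), so the full kernel matrix is precomputed.

#include <Rcpp.h>
#include <random>
using namespace Rcpp;

static inline double rbf(const NumericMatrix& X, int i, int j, double gamma) {
  double s = 0.0;
  for (int c = 0; c < X.ncol(); ++c) {
    double d = X(i, c) - X(j, c);
    s += d * d;
  }
  return std::exp(-gamma * s);
}

// [[Rcpp::export]]
List svm_smo_train(NumericMatrix X, NumericVector y, double C, double gamma,
                   double tol, int max_passes, int seed) {
  const int n = X.nrow();
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j)
      K[(size_t)i * n + j] = K[(size_t)j * n + i] = rbf(X, i, j, gamma);

  std::vector<double> alpha(n, 0.0);
  double b = 0.0;
  std::mt19937 rng(seed);

  auto f = [&](int i) {
    double s = b;
    for (int k = 0; k < n; ++k)
      if (alpha[k] > 0.0) s += alpha[k] * y[k] * K[(size_t)k * n + i];
    return s;
  };

  int passes = 0, iter = 0, max_iter = 200 * std::max(n, 100);
  while (passes < max_passes && iter < max_iter) {
    ++iter;
    int changed = 0;
    for (int i = 0; i < n; ++i) {
      double Ei = f(i) - y[i];
      if ((y[i] * Ei < -tol && alpha[i] < C) ||
          (y[i] * Ei > tol && alpha[i] > 0)) {
        int j = (int)(rng() % (unsigned)(n - 1));
        if (j >= i) ++j;
        double Ej = f(j) - y[j];
        double ai_old = alpha[i], aj_old = alpha[j];
        double L, H;
        if (y[i] != y[j]) {
          L = std::max(0.0, aj_old - ai_old);
          H = std::min(C, C + aj_old - ai_old);
        } else {
          L = std::max(0.0, ai_old + aj_old - C);
          H = std::min(C, ai_old + aj_old);
        }
        if (L >= H) continue;
        double eta = 2.0 * K[(size_t)i * n + j] - K[(size_t)i * n + i] -
                     K[(size_t)j * n + j];
        if (eta >= 0) continue;
        double aj = aj_old - y[j] * (Ei - Ej) / eta;
        aj = std::min(H, std::max(L, aj));
        if (std::fabs(aj - aj_old) < 1e-7) continue;
        double ai = ai_old + y[i] * y[j] * (aj_old - aj);
        alpha[i] = ai;
        alpha[j] = aj;
        double b1 = b - Ei - y[i] * (ai - ai_old) * K[(size_t)i * n + i] -
                    y[j] * (aj - aj_old) * K[(size_t)i * n + j];
        double b2 = b - Ej - y[i] * (ai - ai_old) * K[(size_t)i * n + j] -
                    y[j] * (aj - aj_old) * K[(size_t)j * n + j];
        if (ai > 0 && ai < C) b = b1;
        else if (aj > 0 && aj < C) b = b2;
        else b = 0.5 * (b1 + b2);
        ++changed;
      }
    }
    passes = (changed == 0) ? passes + 1 : 0;
  }
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter);
}

// [[Rcpp::export]]
NumericVector svm_decision(NumericMatrix Xtrain, NumericVector y,
                           NumericVector alpha, double b, double gamma,
                           NumericMatrix Xnew) {
  const int n = Xtrain.nrow(), m = Xnew.nrow(), p = Xtrain.ncol();
  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    double s = b;
    for (int i = 0; i < n; ++i) {
      if (alpha[i] <= 0.0) continue;
      double d2 = 0.0;
      for (int c = 0; c < p; ++c) {
        double d = Xtrain(i, c) - Xnew(q, c);
        d2 += d * d;
      }
      s += alpha[i] * y[i] * std::exp(-gamma * d2);
    }
    out[q] = s;
  }
  return out;
}
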