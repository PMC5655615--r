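#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// r2 of the OLS model on descriptor subset S (centered formulation):
// r2 = b_S' G_SS^{-1} b_S / sstot, where G = X_c' X_c and b = X_c' y_c.
// Solved by an in-place Cholesky on the k x k minor; returns a negative
// value when the minor is not positive definite (collinear subset).
static double subset_r2(const NumericMatrix &G, const NumericVector &b,
                        double sstot, const int *idx, int k,
                        std::vector<double> &L, std::vector<double> &z) {
  // L is k x k scratch (column-major), z length k
  for (int j = 0; j < k; ++j)
    for (int i = j; i < k; ++i)
      L[j * k + i] = G(idx[i], idx[j]);
  // Cholesky
  for (int j = 0; j < k; ++j) {
    double d = L[j * k + j];
    for (int t = 0; t < j; ++t) d -= L[t * k + j] * L[t * k + j];
    if (d <= 1e-12) return -1.0;
    d = std::sqrt(d);
    L[j * k + j] = d;
    for (int i = j + 1; i < k; ++i) {
      double s = L[j * k + i];
      for (int t = 0; t < j; ++t) s -= L[t * k + i] * L[t * k + j];
      L[j * k + i] = s / d;
    }
  }
  // forward solve L z = b_S ; r2 = ||z||^2 / sstot
  double ss = 0.0;
  for (int i = 0; i < k; ++i) {
    double s = b[idx[i]];
    for (int t = 0; t < i; ++t) s -= L[t * k + i] * z[t];
    z[i] = s / L[i * k + i];
    ss += z[i] * z[i];
  }
  return ss / sstot;
}

// [[Rcpp::export(name = ".cppExhaustiveSearch")]]
List cppExhaustiveSearch(NumericMatrix G, NumericVector b, double sstot,
                         int maxVars, int topK) {
  const int p = G.ncol();
  if (maxVars > p) maxVars = p;
  std::vector<double> bestR2(topK, -2.0);
  std::vector<std::vector<int>> bestIdx(topK);
  int worst = 0;            // position of current minimum among kept
  long long nEval = 0;
  std::vector<double> L(maxVars * maxVars);
  std::vector<double> z(maxVars);
  std::vector<int> idx(maxVars);

  for (int k = 1; k <= maxVars; ++k) {
    for (int i = 0; i < k; ++i) idx[i] = i;
    while (true) {
      double r2 = subset_r2(G, b, sstot, idx.data(), k, L, z);
      ++nEval;
      if (r2 > bestR2[worst]) {
        bestR2[worst] = r2;
        bestIdx[worst].assign(idx.begin(), idx.begin() + k);
        worst = 0;
        for (int t = 1; t < topK; ++t)
          if (bestR2[t] < bestR2[worst]) worst = t;
      }
      // next combination of size k out of p
      int pos = k - 1;
      while (pos >= 0 && idx[pos] == p - k + pos) --pos;
      if (pos < 0) break;
      ++idx[pos];
      for (int t = pos + 1; t < k; ++t) idx[t] = idx[t - 1] + 1;
    }
  }
  // order kept models by decreasing r2
  std::vector<int> ord;
  for (int t = 0; t < topK; ++t) if (bestR2[t] > -2.0) ord.push_back(t);
  std::sort(ord.begin(), ord.end(),
            [&](int a, int bb) { return bestR2[a] > bestR2[bb]; });
  IntegerMatrix subsets(ord.size(), maxVars);
  NumericVector r2out(ord.size());
  for (size_t r = 0; r < ord.size(); ++r) {
    r2out[r] = bestR2[ord[r]];
    for (size_t c = 0; c < bestIdx[ord[r]].size(); ++c)
      subsets(r, c) = bestIdx[ord[r]][c] + 1;   // 1-based, 0 = unused
  }
  return List::create(_["subsets"] = subsets, _["r2"] = r2out,
                      _["nEvaluated"] = (double)nEval);
}

// Score a batch of descriptor subsets (rows of `subsets`, 1-based
// indices, 0-padded).  Collinear subsets score 0.
// [[Rcpp::export(name = ".cppScoreSubsets")]]
NumericVector cppScoreSubsets(NumericMatrix G, NumericVector b, double sstot,
                              IntegerMatrix subsets) {
  const int m = subsets.nrow(), w = subsets.ncol();
  NumericVector out(m);
  std::vector<double> L(w * w), z(w);
  std::vector<int> idx(w);
  for (int r = 0; r < m; ++r) {
    int k = 0;
    for (int c = 0; c < w; ++c)
      if (subsets(r, c) > 0) idx[k++] = subsets(r, c) - 1;
    double r2 = (k > 0) ? subset_r2(G, b, sstot, idx.data(), k, L, z) : 0.0;
    out[r] = (r2 < 0) ? 0.0 : r2;
  }
  return out;
}
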