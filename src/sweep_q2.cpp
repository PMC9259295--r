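#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// k-sweep leave-one-out scorer: the annealing hot path.
//
// For a compound-by-descriptor matrix (already restricted to the active
// subset) computes, for every k in 1..kMax, the LOO prediction of each
// compound as the exp(-distance)-weighted mean of its k nearest
// neighbours, and returns the best (q2, k); ties go to the smaller k.
// Distances are plain Euclidean sums of squared differences (no
// cross-product trick), so results agree with the R reference path to
// machine precision. Neighbour ties are broken by ascending compound
// index, matching the R path.
//
// [[Rcpp::export(name = ".sweepQ2Cpp")]]
List sweepQ2Cpp(NumericMatrix x, NumericVector act, int kMax) {
  const int n = x.nrow(), p = x.ncol();
  if (kMax > n - 1) kMax = n - 1;

  long double mean = 0.0;
  for (int i = 0; i < n; ++i) mean += act[i];
  mean /= n;
  long double ssTot = 0.0;
  for (int i = 0; i < n; ++i) {
    const long double d = act[i] - mean;
    ssTot += d * d;
  }
  if (ssTot == 0.0)
    return List::create(_["q2"] = R_NegInf, _["k"] = NA_INTEGER);

  // full distance matrix (row-major block per compound)
  std::vector<double> D(static_cast<size_t>(n) * n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int d = 0; d < p; ++d) {
        const double diff = x(i, d) - x(j, d);
        s += diff * diff;
      }
      const double r = std::sqrt(s);
      D[static_cast<size_t>(i) * n + j] = r;
      D[static_cast<size_t>(j) * n + i] = r;
    }
  }

  // per-compound kMax nearest neighbours (self excluded, ties by index)
  std::vector<double> nnDist(static_cast<size_t>(n) * kMax);
  std::vector<int> nnIdx(static_cast<size_t>(n) * kMax);
  std::vector<int> cand(n - 1);
  for (int i = 0; i < n; ++i) {
    const double *row = &D[static_cast<size_t>(i) * n];
    int m = 0;
    for (int j = 0; j < n; ++j)
      if (j != i) cand[m++] = j;
    std::partial_sort(cand.begin(), cand.begin() + kMax, cand.end(),
                      [row](int a, int b) {
                        if (row[a] != row[b]) return row[a] < row[b];
                        return a < b;
                      });
    for (int k = 0; k < kMax; ++k) {
      nnIdx[static_cast<size_t>(i) * kMax + k] = cand[k];
      nnDist[static_cast<size_t>(i) * kMax + k] = row[cand[k]];
    }
  }

  // incremental weighted predictions over growing k; weights are
  // exp(-(r - r_min)) with r_min the nearest distance (stabilizes
  // exp(-r) underflow; cancels in the normalization)
  std::vector<long double> wSum(n, 0.0), waSum(n, 0.0);
  double bestQ2 = R_NegInf;
  int bestK = NA_INTEGER;
  for (int k = 1; k <= kMax; ++k) {
    long double ssRes = 0.0;
    for (int i = 0; i < n; ++i) {
      const size_t base = static_cast<size_t>(i) * kMax;
      const double w = std::exp(-(nnDist[base + k - 1] - nnDist[base]));
      wSum[i] += w;
      waSum[i] += w * act[nnIdx[base + k - 1]];
      const long double resid = act[i] - waSum[i] / wSum[i];
      ssRes += resid * resid;
    }
    const double q2 = static_cast<double>(1.0L - ssRes / ssTot);
    if (q2 > bestQ2) {
      bestQ2 = q2;
      bestK = k;
    }
  }
  return List::create(_["q2"] = bestQ2, _["k"] = bestK);
}
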