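#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exact k nearest neighbors within one FOV by brute force.
// Points must be pre-sorted by cell_id so that distance ties at the k-th
// neighbor resolve to the lowest cell_id (comparator falls back to index).
// Returns an n x k matrix of 1-based neighbor indices, nearest first.
// [[Rcpp::export]]
IntegerMatrix cpp_knn_indices(NumericVector x, NumericVector y, int k) {
  const int n = x.size();
  if (k <= 0) stop("k must be positive");
  if (k >= n) stop("k must be smaller than the number of points");
  IntegerMatrix out(n, k);
  std::vector<int> idx(n - 1);
  std::vector<double> d2(n);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = x[j] - x[i], dy = y[j] - y[i];
      d2[j] = dx * dx + dy * dy;
      idx[m++] = j;
    }
    std::partial_sort(idx.begin(), idx.begin() + k, idx.end(),
                      [&](int a, int b) {
                        if (d2[a] != d2[b]) return d2[a] < d2[b];
                        return a < b;
                      });
    for (int j = 0; j < k; ++j) out(i, j) = idx[j] + 1;
  }
  return out;
}

// Per-class counts of neighbor points within a closed disc of radius r
// around each index point. Index and neighbor sets may be the same points
// (exclude_self = true skips j == i, valid only for aligned identical sets).
// codes are 0-based class codes of the neighbor points; result is
// n_index x ncls. Boundary is inclusive: d <= r counts.
// [[Rcpp::export]]
IntegerMatrix cpp_radius_class_counts(NumericVector xi, NumericVector yi,
                                      NumericVector xj, NumericVector yj,
                                      IntegerVector codes, int ncls,
                                      double r, bool exclude_self) {
  const int ni = xi.size(), nj = xj.size();
  if (codes.size() != nj) stop("codes length must match neighbor points");
  const double r2 = r * r;
  IntegerMatrix out(ni, ncls);
  for (int i = 0; i < ni; ++i) {
    for (int j = 0; j < nj; ++j) {
      if (exclude_self && j == i) continue;
      const double dx = xj[j] - xi[i], dy = yj[j] - yi[i];
      if (dx * dx + dy * dy <= r2) {
        const int c = codes[j];
        if (c >= 0 && c < ncls) out(i, c) += 1;
      }
    }
  }
  return out;
}

// Number of attractor points within closed radius r of each candidate point.
// [[Rcpp::export]]
IntegerVector cpp_radius_counts(NumericVector xi, NumericVector yi,
                                NumericVector xa, NumericVector ya,
                                double r) {
  const int ni = xi.size(), na = xa.size();
  const double r2 = r * r;
  IntegerVector out(ni);
  for (int i = 0; i < ni; ++i) {
    int cnt = 0;
    for (int j = 0; j < na; ++j) {
      const double dx = xa[j] - xi[i], dy = ya[j] - yi[i];
      if (dx * dx + dy * dy <= r2) ++cnt;
    }
    out[i] = cnt;
  }
  return out;
}
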