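#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Brute-force Euclidean k-nearest-neighbour search. Rows of X are points;
// returns 1-based index matrix (n x k), neighbours ordered by increasing
// distance, ties broken by row index (deterministic). Self is excluded.
// [[Rcpp::export]]
IntegerMatrix cpp_knn(NumericMatrix X, int k) {
  const int n = X.nrow(), d = X.ncol();
  if (k >= n) stop("k must be smaller than the number of points");
  IntegerMatrix out(n, k);
  std::vector<std::pair<double, int> > cand(n - 1);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = X(i, c) - X(j, c);
        s += diff * diff;
      }
      cand[m++] = std::make_pair(s, j);
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int j = 0; j < k; ++j) out(i, j) = cand[j].second + 1;
  }
  return out;
}

// Shared-nearest-neighbour edge list from a kNN index matrix. For each
// ordered pair (i, j) with j among i's neighbours or sharing a neighbour
// with i, the Jaccard overlap of the two k-neighbourhoods (self included)
// is computed; edges with weight below `prune` are dropped. Returns a list
// with 1-based `from`, `to`, `weight` for i < j.
// [[Rcpp::export]]
List cpp_snn_edges(IntegerMatrix nn, double prune) {
  const int n = nn.nrow(), k = nn.ncol();
  // neighbourhood sets including self, sorted
  std::vector<std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i) {
    nb[i].reserve(k + 1);
    nb[i].push_back(i);
    for (int j = 0; j < k; ++j) nb[i].push_back(nn(i, j) - 1);
    std::sort(nb[i].begin(), nb[i].end());
  }
  // candidate pairs: i with each of its neighbours (union handled by set)
  std::vector<int> from, to;
  std::vector<double> w;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < k; ++j) {
      int other = nn(i, j) - 1;
      int a = std::min(i, other), b = std::max(i, other);
      // count intersection of nb[a], nb[b]
      size_t ia = 0, ib = 0; int inter = 0;
      while (ia < nb[a].size() && ib < nb[b].size()) {
        if (nb[a][ia] < nb[b][ib]) ++ia;
        else if (nb[a][ia] > nb[b][ib]) ++ib;
        else { ++inter; ++ia; ++ib; }
      }
      double jac = (double)inter / (double)(2 * (k + 1) - inter);
      if (jac >= prune) {
        from.push_back(a + 1);
        to.push_back(b + 1);
        w.push_back(jac);
      }
    }
  }
  return List::create(_["from"] = from, _["to"] = to, _["weight"] = w);
}
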