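#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <random>
#include <vector>
using namespace Rcpp;

// A compact CART random-forest classifier with out-of-bag permutation
// importance (or Gini impurity-decrease importance). Kept deliberately
// minimal: Gini splits, mtry random features per node, bootstrap per tree.
// Deterministic given `seed`.

namespace {

struct Tree {
  std::vector<int> feature;     // -1 for leaf
  std::vector<double> thresh;
  std::vector<int> left, right; // child node ids
  std::vector<int> pred;        // leaf class
};

int majority(const std::vector<int>& cnt, std::mt19937& rng) {
  int best = 0;
  for (size_t c = 1; c < cnt.size(); ++c)
    if (cnt[c] > cnt[best]) best = (int)c;
  return best;
}

double gini(const std::vector<int>& cnt, int n) {
  if (n == 0) return 0.0;
  double g = 1.0;
  for (size_t c = 0; c < cnt.size(); ++c) {
    double f = (double)cnt[c] / n;
    g -= f * f;
  }
  return g;
}

// predict row i, optionally reading feature `perm_f` from `perm_val`
int predict_row(const Tree& tr, const NumericMatrix& X, int i,
                int perm_f, double perm_val) {
  int node = 0;
  while (tr.feature[node] >= 0) {
    int f = tr.feature[node];
    double v = (f == perm_f) ? perm_val : X(i, f);
    node = (v <= tr.thresh[node]) ? tr.left[node] : tr.right[node];
  }
  return tr.pred[node];
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_rf_importance(NumericMatrix X, IntegerVector y, int K,
                                int ntree, int mtry, int min_node,
                                int seed, bool permutation) {
  const int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> pick_row(0, n - 1);
  NumericVector importance(p);

  std::vector<int> feat_pool(p);
  std::iota(feat_pool.begin(), feat_pool.end(), 0);

  for (int t = 0; t < ntree; ++t) {
    // bootstrap
    std::vector<int> idx(n);
    std::vector<char> inbag(n, 0);
    for (int i = 0; i < n; ++i) {
      idx[i] = pick_row(rng);
      inbag[idx[i]] = 1;
    }

    Tree tr;
    std::vector<char> used(p, 0);
    // stack of (node_id, begin, end) over idx
    struct Frame { int node, b, e; };
    std::vector<Frame> stack;
    tr.feature.push_back(-1); tr.thresh.push_back(0.0);
    tr.left.push_back(-1); tr.right.push_back(-1); tr.pred.push_back(0);
    stack.push_back({0, 0, n});

    std::vector<double> vals;
    std::vector<int> order_buf;
    while (!stack.empty()) {
      Frame fr = stack.back(); stack.pop_back();
      int m = fr.e - fr.b;
      std::vector<int> cnt(K, 0);
      for (int i = fr.b; i < fr.e; ++i) cnt[y[idx[i]]]++;
      int maj = majority(cnt, rng);
      bool pure = cnt[maj] == m;
      if (pure || m < min_node) {
        tr.feature[fr.node] = -1;
        tr.pred[fr.node] = maj;
        continue;
      }
      // sample mtry features without replacement (partial Fisher-Yates)
      for (int j = 0; j < mtry; ++j) {
        std::uniform_int_distribution<int> pick(j, p - 1);
        std::swap(feat_pool[j], feat_pool[pick(rng)]);
      }
      double node_gini = gini(cnt, m);
      double best_gain = 1e-12;
      int best_f = -1;
      double best_thr = 0.0;
      for (int j = 0; j < mtry; ++j) {
        int f = feat_pool[j];
        order_buf.resize(m);
        std::iota(order_buf.begin(), order_buf.end(), fr.b);
        std::sort(order_buf.begin(), order_buf.end(),
                  [&](int a, int b) { return X(idx[a], f) < X(idx[b], f); });
        std::vector<int> lc(K, 0), rc(cnt);
        int nl = 0;
        for (int r = 0; r < m - 1; ++r) {
          int row = idx[order_buf[r]];
          lc[y[row]]++; rc[y[row]]--; nl++;
          double v = X(row, f), vnext = X(idx[order_buf[r + 1]], f);
          if (v == vnext) continue;
          double gain = node_gini -
            ((double)nl / m) * gini(lc, nl) -
            ((double)(m - nl) / m) * gini(rc, m - nl);
          if (gain > best_gain) {
            best_gain = gain;
            best_f = f;
            best_thr = 0.5 * (v + vnext);
          }
        }
      }
      if (best_f < 0) {
        tr.feature[fr.node] = -1;
        tr.pred[fr.node] = maj;
        continue;
      }
      if (!permutation) importance[best_f] += ((double)m / n) * best_gain;
      used[best_f] = 1;
      // partition idx[b, e) by the chosen split
      int mid = fr.b;
      for (int i = fr.b; i < fr.e; ++i)
        if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
      int L = (int)tr.feature.size();
      tr.feature.push_back(-1); tr.thresh.push_back(0.0);
      tr.left.push_back(-1); tr.right.push_back(-1); tr.pred.push_back(0);
      int R = (int)tr.feature.size();
      tr.feature.push_back(-1); tr.thresh.push_back(0.0);
      tr.left.push_back(-1); tr.right.push_back(-1); tr.pred.push_back(0);
      tr.feature[fr.node] = best_f;
      tr.thresh[fr.node] = best_thr;
      tr.left[fr.node] = L;
      tr.right[fr.node] = R;
      stack.push_back({L, fr.b, mid});
      stack.push_back({R, mid, fr.e});
    }

    if (permutation) {
      std::vector<int> oob;
      for (int i = 0; i < n; ++i) if (!inbag[i]) oob.push_back(i);
      if (oob.empty()) continue;
      int correct = 0;
      for (int i : oob)
        if (predict_row(tr, X, i, -1, 0.0) == y[i]) ++correct;
      // permute each in-tree feature among the OOB rows
      std::vector<int> perm(oob);
      for (int f = 0; f < p; ++f) {
        if (!used[f]) continue;
        std::shuffle(perm.begin(), perm.end(), rng);
        int correct_perm = 0;
        for (size_t i = 0; i < oob.size(); ++i)
          if (predict_row(tr, X, oob[i], f, X(perm[i], f)) == y[oob[i]])
            ++correct_perm;
        importance[f] +=
          (double)(correct - correct_perm) / (double)oob.size();
      }
    }
  }
  for (int f = 0; f < p; ++f) importance[f] /= ntree;
  return importance;
}
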