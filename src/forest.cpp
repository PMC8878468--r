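// Seeded bagged-CART ensemble (gini splits, class-probability leaves).
// Fitted trees are returned as plain numeric vectors so a GatingModel can
// be serialized to JSON and reloaded bit-stably.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct TreeBuf {
  std::vector<int> feat;      // split feature (0-based), -1 for leaf
  std::vector<double> thr;    // go left if x <= thr
  std::vector<int> left, right;
  std::vector<double> probs;  // nclass per node (leaf payload)
};

struct Builder {
  const NumericMatrix &X;
  const IntegerVector &y; // 0..K-1
  int K, mtry, min_leaf, max_depth;
  std::mt19937 &rng;
  TreeBuf &tb;

  int new_node(const std::vector<int> &idx) {
    int id = tb.feat.size();
    tb.feat.push_back(-1);
    tb.thr.push_back(0.0);
    tb.left.push_back(-1);
    tb.right.push_back(-1);
    std::vector<double> cnt(K, 0.0);
    for (int i : idx) cnt[y[i]] += 1.0;
    double n = idx.size();
    for (int k = 0; k < K; ++k) tb.probs.push_back(cnt[k] / std::max(1.0, n));
    return id;
  }

  static double gini_from_counts(const std::vector<double> &cnt, double n) {
    if (n <= 0) return 0.0;
    double g = 1.0;
    for (double c : cnt) g -= (c / n) * (c / n);
    return g;
  }

  int build(std::vector<int> &idx, int depth) {
    int id = new_node(idx);
    int n = idx.size();
    bool pure = true;
    for (int i = 1; i < n; ++i)
      if (y[idx[i]] != y[idx[0]]) { pure = false; break; }
    if (pure || depth >= max_depth || n < 2 * min_leaf) return id;

    int p = X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    // sample mtry features without replacement
    for (int j = 0; j < mtry && j < p; ++j) {
      std::uniform_int_distribution<int> u(j, p - 1);
      std::swap(feats[j], feats[u(rng)]);
    }
    int m = std::min(mtry, p);

    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<double> tot(K, 0.0);
    for (int i : idx) tot[y[i]] += 1.0;
    double g0 = gini_from_counts(tot, n);

    std::vector<std::pair<double, int>> vals(n);
    for (int jj = 0; jj < m; ++jj) {
      int f = feats[jj];
      for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], f), y[idx[i]]};
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      std::vector<double> lc(K, 0.0);
      double nl = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        lc[vals[i].second] += 1.0;
        nl += 1.0;
        if (vals[i].first == vals[i + 1].first) continue;
        if (nl < min_leaf || n - nl < min_leaf) continue;
        std::vector<double> rc(K);
        for (int k = 0; k < K; ++k) rc[k] = tot[k] - lc[k];
        double g = g0 - (nl / n) * gini_from_counts(lc, nl) -
                   ((n - nl) / n) * gini_from_counts(rc, n - nl);
        if (g > best_gain) {
          best_gain = g;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) return id;

    std::vector<int> li, ri;
    for (int i : idx)
      (X(i, best_f) <= best_thr ? li : ri).push_back(i);
    if ((int)li.size() < min_leaf || (int)ri.size() < min_leaf) return id;
    tb.feat[id] = best_f;
    tb.thr[id] = best_thr;
    int l = build(li, depth + 1);
    int r = build(ri, depth + 1);
    tb.left[id] = l;
    tb.right[id] = r;
    return id;
  }
};

} // namespace

// [[Rcpp::export(name = ".forest_fit_cpp")]]
List forest_fit_cpp(NumericMatrix X, IntegerVector y, int nclass, int ntree,
                    int mtry, int min_leaf, int max_depth, int seed) {
  int n = X.nrow();
  std::mt19937 rng((unsigned)seed);
  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    std::uniform_int_distribution<int> u(0, n - 1);
    for (int i = 0; i < n; ++i) idx[i] = u(rng);
    TreeBuf tb;
    Builder b{X, y, nclass, mtry, min_leaf, max_depth, rng, tb};
    b.build(idx, 0);
    trees[t] = List::create(
        _["feat"] = IntegerVector(tb.feat.begin(), tb.feat.end()),
        _["thr"] = NumericVector(tb.thr.begin(), tb.thr.end()),
        _["left"] = IntegerVector(tb.left.begin(), tb.left.end()),
        _["right"] = IntegerVector(tb.right.begin(), tb.right.end()),
        _["probs"] = NumericVector(tb.probs.begin(), tb.probs.end()));
  }
  return trees;
}

// [[Rcpp::export(name = ".forest_predict_cpp")]]
NumericMatrix forest_predict_cpp(List trees, NumericMatrix X, int nclass) {
  int n = X.nrow(), T = trees.size();
  NumericMatrix out(n, nclass);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feat = tr["feat"];
    NumericVector thr = tr["thr"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector probs = tr["probs"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feat[node] >= 0) {
        node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
      }
      for (int k = 0; k < nclass; ++k)
        out(i, k) += probs[node * nclass + k];
    }
  }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < nclass; ++k) out(i, k) /= T;
  return out;
}
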