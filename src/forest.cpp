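// Classification random forest: CART trees with Gini splits, bootstrap
// bagging, per-split feature subsampling, Gini importances and OOB votes.
// Uses R's RNG (seed with set.seed() before calling) so results are
// reproducible across platforms.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct TreeNodes {
  std::vector<int> feature;       // -1 for leaves
  std::vector<double> threshold;
  std::vector<int> left, right;   // child node ids, -1 for leaves
  std::vector<std::vector<double>> prob; // class distribution per node
};

inline int runif_int(int n) {
  // uniform integer in [0, n)
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

double gini(const std::vector<double>& cnt, double n) {
  if (n <= 0) return 0.0;
  double s = 0.0;
  for (double c : cnt) s += c * c;
  return 1.0 - s / (n * n);
}

struct GrowContext {
  const NumericMatrix& X;
  const IntegerVector& y;
  int nclass, mtry, min_node, max_depth;
  std::vector<double>& importance;
  TreeNodes& tree;
};

// recursively grow; idx are in-bag sample row indices (with repeats)
int grow(GrowContext& ctx, std::vector<int>& idx, int depth) {
  const int n = (int)idx.size();
  std::vector<double> cnt(ctx.nclass, 0.0);
  for (int i : idx) cnt[ctx.y[i]] += 1.0;

  int node = (int)ctx.tree.feature.size();
  ctx.tree.feature.push_back(-1);
  ctx.tree.threshold.push_back(0.0);
  ctx.tree.left.push_back(-1);
  ctx.tree.right.push_back(-1);
  std::vector<double> p(ctx.nclass, 0.0);
  for (int c = 0; c < ctx.nclass; ++c) p[c] = cnt[c] / n;
  ctx.tree.prob.push_back(p);

  double g_parent = gini(cnt, n);
  bool pure = g_parent <= 0.0;
  if (pure || n < 2 * ctx.min_node || n < 2 || depth >= ctx.max_depth)
    return node;

  const int pdim = ctx.X.ncol();
  // sample mtry distinct features (partial Fisher-Yates)
  std::vector<int> feats(pdim);
  for (int j = 0; j < pdim; ++j) feats[j] = j;
  int m = std::min(ctx.mtry, pdim);
  for (int j = 0; j < m; ++j)
    std::swap(feats[j], feats[j + runif_int(pdim - j)]);

  double best_dec = 0.0, best_thr = 0.0;
  int best_f = -1;
  std::vector<int> ord(idx);
  for (int j = 0; j < m; ++j) {
    const int f = feats[j];
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return ctx.X(a, f) < ctx.X(b, f);
    });
    std::vector<double> lcnt(ctx.nclass, 0.0);
    for (int i = 1; i < n; ++i) {
      lcnt[ctx.y[ord[i - 1]]] += 1.0;
      double xl = ctx.X(ord[i - 1], f), xr = ctx.X(ord[i], f);
      if (xr <= xl) continue;
      if (i < ctx.min_node || n - i < ctx.min_node) continue;
      std::vector<double> rcnt(ctx.nclass, 0.0);
      for (int c = 0; c < ctx.nclass; ++c) rcnt[c] = cnt[c] - lcnt[c];
      double g = (i * gini(lcnt, i) + (n - i) * gini(rcnt, n - i)) / n;
      double dec = g_parent - g;
      if (dec > best_dec + 1e-12) {
        best_dec = dec;
        best_f = f;
        best_thr = 0.5 * (xl + xr);
      }
    }
  }
  if (best_f < 0) return node;

  ctx.importance[best_f] += n * best_dec;
  std::vector<int> lidx, ridx;
  lidx.reserve(n);
  ridx.reserve(n);
  for (int i : idx) {
    if (ctx.X(i, best_f) <= best_thr) lidx.push_back(i);
    else ridx.push_back(i);
  }
  ctx.tree.feature[node] = best_f;
  ctx.tree.threshold[node] = best_thr;
  ctx.tree.left[node] = grow(ctx, lidx, depth + 1);
  ctx.tree.right[node] = grow(ctx, ridx, depth + 1);
  return node;
}

int descend(const IntegerVector& feature, const NumericVector& threshold,
            const IntegerVector& left, const IntegerVector& right,
            const NumericMatrix& X, int row) {
  int node = 0;
  while (feature[node] >= 0) {
    node = (X(row, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
  }
  return node;
}

} // namespace

// [[Rcpp::export]]
List cpp_rf_train(NumericMatrix X, IntegerVector y, int nclass, int ntree,
                  int mtry, int min_node, int max_depth) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> importance(p, 0.0);
  NumericMatrix oob_prob(n, nclass);
  std::vector<int> oob_n(n, 0);
  List trees(ntree);

  for (int t = 0; t < ntree; ++t) {
    std::vector<int> inbag_count(n, 0);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      idx[i] = runif_int(n);
      inbag_count[idx[i]]++;
    }
    TreeNodes tree;
    GrowContext ctx{X, y, nclass, mtry, min_node, max_depth,
                    importance, tree};
    grow(ctx, idx, 0);

    const int nn = (int)tree.feature.size();
    IntegerVector feature(nn), left(nn), right(nn);
    NumericVector threshold(nn);
    NumericMatrix prob(nn, nclass);
    for (int k = 0; k < nn; ++k) {
      feature[k] = tree.feature[k];
      threshold[k] = tree.threshold[k];
      left[k] = tree.left[k];
      right[k] = tree.right[k];
      for (int c = 0; c < nclass; ++c) prob(k, c) = tree.prob[k][c];
    }
    for (int i = 0; i < n; ++i) {
      if (inbag_count[i] == 0) {
        int leaf = descend(feature, threshold, left, right, X, i);
        for (int c = 0; c < nclass; ++c) oob_prob(i, c) += prob(leaf, c);
        oob_n[i]++;
      }
    }
    trees[t] = List::create(_["feature"] = feature,
                            _["threshold"] = threshold,
                            _["left"] = left, _["right"] = right,
                            _["prob"] = prob);
  }
  for (int i = 0; i < n; ++i) {
    if (oob_n[i] > 0)
      for (int c = 0; c < nclass; ++c) oob_prob(i, c) /= oob_n[i];
  }
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = importance[j] / ntree;
  return List::create(_["trees"] = trees, _["importance"] = imp,
                      _["oob_prob"] = oob_prob,
                      _["oob_n"] = IntegerVector(oob_n.begin(), oob_n.end()));
}

// [[Rcpp::export]]
NumericMatrix cpp_rf_predict(List trees, NumericMatrix X, int nclass) {
  const int n = X.nrow(), ntree = trees.size();
  NumericMatrix out(n, nclass);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"],
                  right = tr["right"];
    NumericVector threshold = tr["threshold"];
    NumericMatrix prob = tr["prob"];
    for (int i = 0; i < n; ++i) {
      int leaf = descend(feature, threshold, left, right, X, i);
      for (int c = 0; c < nclass; ++c) out(i, c) += prob(leaf, c);
    }
  }
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < nclass; ++c) out(i, c) /= ntree;
  return out;
}
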