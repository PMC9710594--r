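#include <Rcpp.h>
#include <random>
#include <algorithm>
using namespace Rcpp;

// Class-weighted random forest for binary classification (CART, Gini).
// Trees are returned as flat node tables so that a fitted forest is plain
// data (JSON-serializable) and prediction needs no opaque handle.
//
// Node table columns:
//   0 feature (1-based; 0 => leaf)   1 threshold (left: x < thr)
//   2 left child row (1-based)       3 right child row
//   4 weighted count class 0         5 weighted count class 1

namespace {

struct Node {
  int feature = 0;        // 0 = leaf
  double threshold = 0.0;
  int left = 0, right = 0;
  double w0 = 0.0, w1 = 0.0;
};

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  const NumericVector& w;
  int min_split, mtry;
  double w_total;
  std::mt19937 rng;
  std::vector<Node> nodes;
  std::vector<double>& importance;   // accumulated across trees

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_,
              const NumericVector& w_, int min_split_, int mtry_,
              double w_total_, unsigned seed, std::vector<double>& imp)
      : X(X_), y(y_), w(w_), min_split(min_split_), mtry(mtry_),
        w_total(w_total_), rng(seed), importance(imp) {}

  static double gini(double w0, double w1) {
    double W = w0 + w1;
    if (W <= 0.0) return 0.0;
    double p0 = w0 / W, p1 = w1 / W;
    return 1.0 - p0 * p0 - p1 * p1;
  }

  int build(std::vector<int>& idx) {
    double w0 = 0.0, w1 = 0.0;
    for (int i : idx) { if (y[i] == 0) w0 += w[i]; else w1 += w[i]; }
    int me = (int)nodes.size();
    nodes.push_back(Node());
    nodes[me].w0 = w0; nodes[me].w1 = w1;

    const int n = (int)idx.size();
    if (n < min_split || w0 == 0.0 || w1 == 0.0) return me;

    // sample mtry candidate features without replacement
    const int p = X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    for (int j = 0; j < mtry && j < p; ++j) {
      std::uniform_int_distribution<int> pick(j, p - 1);
      std::swap(feats[j], feats[pick(rng)]);
    }

    double parent_imp = gini(w0, w1);
    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<int> ord(idx);

    for (int fj = 0; fj < mtry && fj < p; ++fj) {
      int f = feats[fj];
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        double xa = X(a, f), xb = X(b, f);
        if (xa != xb) return xa < xb;
        return a < b;
      });
      double lw0 = 0.0, lw1 = 0.0;
      for (int k = 0; k < n - 1; ++k) {
        int i = ord[k];
        if (y[i] == 0) lw0 += w[i]; else lw1 += w[i];
        double xk = X(i, f), xk1 = X(ord[k + 1], f);
        if (xk == xk1) continue;
        double rw0 = w0 - lw0, rw1 = w1 - lw1;
        double wl = lw0 + lw1, wr = rw0 + rw1;
        double child = (wl * gini(lw0, lw1) + wr * gini(rw0, rw1)) / (w0 + w1);
        double gain = parent_imp - child;
        if (gain > best_gain) {
          best_gain = gain; best_f = f;
          best_thr = 0.5 * (xk + xk1);
          if (best_thr <= xk) best_thr = xk1;  // numeric degeneracy guard
        }
      }
    }
    if (best_f < 0) return me;

    std::vector<int> li, ri;
    li.reserve(n); ri.reserve(n);
    for (int i : idx) {
      if (X(i, best_f) < best_thr) li.push_back(i); else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) return me;

    importance[best_f] += (w0 + w1) / w_total * best_gain;
    nodes[me].feature = best_f + 1;
    nodes[me].threshold = best_thr;
    int l = build(li);
    int r = build(ri);
    nodes[me].left = l + 1;
    nodes[me].right = r + 1;
    return me;
  }
};

} // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, NumericVector w,
                int n_trees, int min_split, int mtry, int seed) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> importance(p, 0.0);
  List trees(n_trees);

  for (int t = 0; t < n_trees; ++t) {
    unsigned s = (unsigned)seed * 2654435761u + 97u * (unsigned)t + 1u;
    std::mt19937 boot_rng(s);
    std::uniform_int_distribution<int> pick(0, n - 1);
    std::vector<int> idx(n);
    double w_total = 0.0;
    for (int i = 0; i < n; ++i) { idx[i] = pick(boot_rng); }
    for (int i : idx) w_total += w[i];

    TreeBuilder tb(X, y, w, min_split, mtry, w_total, s ^ 0x9e3779b9u,
                   importance);
    tb.build(idx);

    NumericMatrix tm((int)tb.nodes.size(), 6);
    for (size_t k = 0; k < tb.nodes.size(); ++k) {
      const Node& nd = tb.nodes[k];
      tm(k, 0) = nd.feature; tm(k, 1) = nd.threshold;
      tm(k, 2) = nd.left; tm(k, 3) = nd.right;
      tm(k, 4) = nd.w0; tm(k, 5) = nd.w1;
    }
    trees[t] = tm;
  }

  NumericVector imp(p);
  double tot = 0.0;
  for (int j = 0; j < p; ++j) tot += importance[j];
  for (int j = 0; j < p; ++j) imp[j] = tot > 0 ? importance[j] / tot : 0.0;
  return List::create(_["trees"] = trees, _["importance"] = imp);
}

// Fraction of trees voting class 1 (leaf weighted majority; tie -> class 0).
// [[Rcpp::export]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), T = trees.size();
  NumericVector score(n);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (tm(node, 0) > 0) {
        int f = (int)tm(node, 0) - 1;
        node = (X(i, f) < tm(node, 1)) ? (int)tm(node, 2) - 1
                                       : (int)tm(node, 3) - 1;
      }
      if (tm(node, 5) > tm(node, 4)) score[i] += 1.0;
    }
  }
  for (int i = 0; i < n; ++i) score[i] /= (double)T;
  return score;
}
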