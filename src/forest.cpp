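// Random forest classifier (binary, Gini criterion) used for per-trial
// decision-confidence estimation. Matches the usual bagging recipe:
// bootstrap-resampled fully grown CART trees, feature subsampling at each
// split, probabilities averaged over trees (mean of per-tree leaf class
// fractions). Deterministic given `seed` (std::mt19937_64, platform stable).

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Node {
  int feature;     // -1 for leaf
  double threshold;
  int left, right; // child indices, -1 for leaf
  double p1;       // weighted fraction of class 1 (leaf payload)
};

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;      // 0/1
  const std::vector<double>& w; // per-observation weight (class weights)
  int mtry;
  int min_leaf;
  std::mt19937_64 rng;
  std::vector<Node> nodes;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_,
              const std::vector<double>& w_, int mtry_, int min_leaf_,
              uint64_t seed)
    : X(X_), y(y_), w(w_), mtry(mtry_), min_leaf(min_leaf_), rng(seed) {}

  double leaf_p1(const std::vector<int>& idx) const {
    double w1 = 0.0, wt = 0.0;
    for (int i : idx) { wt += w[i]; if (y[i] == 1) w1 += w[i]; }
    return wt > 0 ? w1 / wt : 0.5;
  }

  bool pure(const std::vector<int>& idx) const {
    for (size_t k = 1; k < idx.size(); ++k)
      if (y[idx[k]] != y[idx[0]]) return false;
    return true;
  }

  // Returns node index in `nodes`.
  int build(std::vector<int>& idx) {
    Node nd; nd.feature = -1; nd.threshold = 0.0; nd.left = nd.right = -1;
    nd.p1 = leaf_p1(idx);
    if ((int)idx.size() < 2 * min_leaf || pure(idx)) {
      nodes.push_back(nd);
      return (int)nodes.size() - 1;
    }

    int p = X.ncol();
    // sample mtry features without replacement
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    for (int j = 0; j < mtry && j < p; ++j) {
      std::uniform_int_distribution<int> u(j, p - 1);
      std::swap(feats[j], feats[u(rng)]);
    }

    double w1_tot = 0.0, w_tot = 0.0;
    for (int i : idx) { w_tot += w[i]; if (y[i] == 1) w1_tot += w[i]; }
    double parent_gini = 0.0;
    {
      double q = w1_tot / w_tot;
      parent_gini = 2.0 * q * (1.0 - q);
    }

    int best_feat = -1; double best_thr = 0.0, best_gain = 1e-12;
    std::vector<std::pair<double,int>> vals(idx.size());
    for (int jj = 0; jj < mtry && jj < p; ++jj) {
      int j = feats[jj];
      for (size_t k = 0; k < idx.size(); ++k)
        vals[k] = std::make_pair(X(idx[k], j), idx[k]);
      std::sort(vals.begin(), vals.end());
      double wl = 0.0, wl1 = 0.0;
      for (size_t k = 0; k + 1 < vals.size(); ++k) {
        int i = vals[k].second;
        wl += w[i]; if (y[i] == 1) wl1 += w[i];
        if (vals[k + 1].first <= vals[k].first) continue; // not a valid cut
        if ((int)(k + 1) < min_leaf || (int)(vals.size() - k - 1) < min_leaf)
          continue;
        double wr = w_tot - wl, wr1 = w1_tot - wl1;
        double ql = wl1 / wl, qr = wr1 / wr;
        double child = (wl * 2.0 * ql * (1.0 - ql) +
                        wr * 2.0 * qr * (1.0 - qr)) / w_tot;
        double gain = parent_gini - child;
        if (gain > best_gain) {
          best_gain = gain;
          best_feat = j;
          best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
        }
      }
    }

    if (best_feat < 0) { // no useful split among sampled features
      nodes.push_back(nd);
      return (int)nodes.size() - 1;
    }

    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_feat) <= best_thr) li.push_back(i); else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) {
      nodes.push_back(nd);
      return (int)nodes.size() - 1;
    }
    nd.feature = best_feat; nd.threshold = best_thr;
    nodes.push_back(nd);
    int me = (int)nodes.size() - 1;
    int l = build(li);
    int r = build(ri);
    nodes[me].left = l; nodes[me].right = r;
    return me;
  }
};

NumericMatrix pack_tree(const std::vector<Node>& nodes) {
  NumericMatrix m(nodes.size(), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    m(i, 0) = nodes[i].feature;
    m(i, 1) = nodes[i].threshold;
    m(i, 2) = nodes[i].left;
    m(i, 3) = nodes[i].right;
    m(i, 4) = nodes[i].p1;
  }
  return m;
}

double predict_tree(const NumericMatrix& tree, const NumericMatrix& X, int row,
                    int node = 0) {
  while (tree(node, 0) >= 0) {
    int f = (int)tree(node, 0);
    node = (X(row, f) <= tree(node, 1)) ? (int)tree(node, 2)
                                        : (int)tree(node, 3);
  }
  return tree(node, 4);
}

} // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                int min_leaf, NumericVector class_weights, int seed) {
  int n = X.nrow();
  if (y.size() != n) stop("X/y size mismatch");
  std::vector<double> w(n);
  for (int i = 0; i < n; ++i) w[i] = class_weights[y[i] == 1 ? 1 : 0];

  List trees(n_trees);
  std::mt19937_64 master((uint64_t)seed);
  for (int t = 0; t < n_trees; ++t) {
    uint64_t tree_seed = master();
    std::mt19937_64 boot(tree_seed);
    std::uniform_int_distribution<int> u(0, n - 1);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = u(boot);
    TreeBuilder tb(X, y, w, mtry, min_leaf, boot());
    tb.build(idx);
    trees[t] = pack_tree(tb.nodes);
  }
  return List::create(_["trees"] = trees, _["n_features"] = X.ncol());
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  List trees = forest["trees"];
  int nt = trees.size(), n = X.nrow();
  NumericVector out(n);
  for (int t = 0; t < nt; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) out[i] += predict_tree(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= nt;
  return out;
}

// Biquad cascade (second-order sections) applied forward; used by the
// zero-phase filtfilt wrapper on the R side. sos: k x 6 (b0 b1 b2 a0 a1 a2).
// [[Rcpp::export(name = ".sosfilt_cpp")]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x) {
  int ns = sos.nrow(), n = x.size();
  NumericVector y = clone(x);
  for (int s = 0; s < ns; ++s) {
    double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    double a0 = sos(s, 3), a1 = sos(s, 4), a2 = sos(s, 5);
    b0 /= a0; b1 /= a0; b2 /= a0; a1 /= a0; a2 /= a0;
    // steady-state (step-response) initial conditions scaled by the first
    // sample, so constant inputs produce their steady-state output exactly
    double yss = (b0 + b1 + b2) / (1.0 + a1 + a2);
    double z1 = (yss - b0) * y[0];
    double z2 = (b2 - a2 * yss) * y[0];
    for (int i = 0; i < n; ++i) {
      double xi = y[i];
      double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}

// Zero-phase FIR + decimation fused kernel. h must be odd-length symmetric
// (linear phase); edges are odd-reflected. Computes only the retained
// samples: original indices first, first+q, ... (1-based `first`).
// [[Rcpp::export(name = ".fir_decim_cpp")]]
NumericMatrix fir_decim_cpp(NumericMatrix x, NumericVector h, int q,
                            int first) {
  int n = x.nrow(), m = x.ncol(), L = h.size(), M = (L - 1) / 2;
  int n_out = (n - first) / q + 1;
  NumericMatrix y(n_out, m);
  for (int c = 0; c < m; ++c) {
    const double* xc = &x(0, c);
    for (int j = 0; j < n_out; ++j) {
      int t = (first - 1) + j * q;
      double acc = 0.0;
      for (int k = 0; k < L; ++k) {
        int i = t + M - k;
        double v;
        if (i < 0) v = 2.0 * xc[0] - xc[-i];
        else if (i >= n) v = 2.0 * xc[n - 1] - xc[2 * n - 2 - i];
        else v = xc[i];
        acc += h[k] * v;
      }
      y(j, c) = acc;
    }
  }
  return y;
}
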