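// Exact greedy regression-tree builder for the boosting ensemble.
// Second-order split gain with L1/L2 leaf penalties and a per-node
// complexity charge; every internal node learns a default direction for
// missing values (the direction with the higher gain).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

struct Node {
  int feature = -1;        // -1: leaf
  double threshold = 0.0;  // go left iff x < threshold
  bool missing_left = true;
  int left = -1, right = -1;
  double value = 0.0;      // leaf weight (unscaled by learning rate)
};

static inline double thresh_l1(double g, double alpha) {
  if (g > alpha) return g - alpha;
  if (g < -alpha) return g + alpha;
  return 0.0;
}

static inline double leaf_score(double g, double h, double lambda,
                                double alpha) {
  double t = thresh_l1(g, alpha);
  return t * t / (h + lambda);
}

static inline double leaf_weight(double g, double h, double lambda,
                                 double alpha) {
  return -thresh_l1(g, alpha) / (h + lambda);
}

struct Builder {
  const NumericMatrix& X;
  const NumericVector& grad;
  const NumericVector& hess;
  double lambda, alpha, gamma;
  int max_depth;
  double colsample;
  std::mt19937 rng;
  std::vector<Node> nodes;

  Builder(const NumericMatrix& X_, const NumericVector& g_,
          const NumericVector& h_, double lambda_, double alpha_,
          double gamma_, int max_depth_, double colsample_, unsigned seed)
      : X(X_), grad(g_), hess(h_), lambda(lambda_), alpha(alpha_),
        gamma(gamma_), max_depth(max_depth_), colsample(colsample_),
        rng(seed) {}

  std::vector<int> sample_features() {
    int p = X.ncol();
    int take = std::max(1, (int)std::ceil(colsample * p));
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    if (take >= p) return feats;
    // partial Fisher-Yates
    for (int i = 0; i < take; ++i) {
      std::uniform_int_distribution<int> d(i, p - 1);
      std::swap(feats[i], feats[d(rng)]);
    }
    feats.resize(take);
    std::sort(feats.begin(), feats.end());
    return feats;
  }

  int build(const std::vector<int>& rows, int depth) {
    double G = 0.0, H = 0.0;
    for (int r : rows) { G += grad[r]; H += hess[r]; }
    int id = (int)nodes.size();
    nodes.push_back(Node());
    if (depth >= max_depth || rows.size() < 2) {
      nodes[id].value = leaf_weight(G, H, lambda, alpha);
      return id;
    }
    double parent = leaf_score(G, H, lambda, alpha);
    double best_gain = 0.0, best_thr = 0.0;
    int best_f = -1;
    bool best_missing_left = true;
    std::vector<int> feats = sample_features();
    std::vector<std::pair<double, int>> vals;
    for (int f : feats) {
      vals.clear();
      double Gm = 0.0, Hm = 0.0;  // missing-value totals
      for (int r : rows) {
        double x = X(r, f);
        if (ISNAN(x)) { Gm += grad[r]; Hm += hess[r]; }
        else vals.push_back({x, r});
      }
      if (vals.size() < 2) continue;
      std::sort(vals.begin(), vals.end());
      double GL = 0.0, HL = 0.0;
      double Gn = G - Gm, Hn = H - Hm;  // non-missing totals
      for (size_t i = 0; i + 1 < vals.size(); ++i) {
        GL += grad[vals[i].second];
        HL += hess[vals[i].second];
        if (vals[i + 1].first == vals[i].first) continue;
        double GR = Gn - GL, HR = Hn - HL;
        double thr = 0.5 * (vals[i].first + vals[i + 1].first);
        double s_ml = leaf_score(GL + Gm, HL + Hm, lambda, alpha) +
                      leaf_score(GR, HR, lambda, alpha);
        double s_mr = leaf_score(GL, HL, lambda, alpha) +
                      leaf_score(GR + Gm, HR + Hm, lambda, alpha);
        bool ml = s_ml >= s_mr;
        double gain = 0.5 * ((ml ? s_ml : s_mr) - parent) - gamma;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_f = f;
          best_thr = thr;
          best_missing_left = ml;
        }
      }
    }
    if (best_f < 0) {
      nodes[id].value = leaf_weight(G, H, lambda, alpha);
      return id;
    }
    std::vector<int> lrows, rrows;
    for (int r : rows) {
      double x = X(r, best_f);
      bool go_left = ISNAN(x) ? best_missing_left : (x < best_thr);
      (go_left ? lrows : rrows).push_back(r);
    }
    if (lrows.empty() || rrows.empty()) {  // degenerate; make a leaf
      nodes[id].value = leaf_weight(G, H, lambda, alpha);
      return id;
    }
    nodes[id].feature = best_f;
    nodes[id].threshold = best_thr;
    nodes[id].missing_left = best_missing_left;
    int l = build(lrows, depth + 1);
    int rr = build(rrows, depth + 1);
    nodes[id].left = l;
    nodes[id].right = rr;
    return id;
  }
};

// [[Rcpp::export]]
List gbt_build_tree_cpp(NumericMatrix X, NumericVector grad,
                        NumericVector hess, IntegerVector rows,
                        double lambda, double alpha, double gamma,
                        int max_depth, double colsample, int seed) {
  Builder b(X, grad, hess, lambda, alpha, gamma, max_depth, colsample,
            (unsigned)seed);
  std::vector<int> rws(rows.begin(), rows.end());
  b.build(rws, 0);
  int n = (int)b.nodes.size();
  IntegerVector feature(n), left(n), right(n);
  NumericVector threshold(n), value(n);
  LogicalVector missing_left(n);
  for (int i = 0; i < n; ++i) {
    feature[i] = b.nodes[i].feature < 0 ? NA_INTEGER : b.nodes[i].feature + 1;
    threshold[i] = b.nodes[i].threshold;
    missing_left[i] = b.nodes[i].missing_left;
    left[i] = b.nodes[i].left < 0 ? NA_INTEGER : b.nodes[i].left + 1;
    right[i] = b.nodes[i].right < 0 ? NA_INTEGER : b.nodes[i].right + 1;
    value[i] = b.nodes[i].value;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["missing_left"] = missing_left, _["left"] = left,
                      _["right"] = right, _["value"] = value);
}

// [[Rcpp::export]]
NumericVector gbt_predict_tree_cpp(NumericMatrix X, IntegerVector feature,
                                   NumericVector threshold,
                                   LogicalVector missing_left,
                                   IntegerVector left, IntegerVector right,
                                   NumericVector value) {
  int n = X.nrow();
  NumericVector out(n);
  for (int r = 0; r < n; ++r) {
    int node = 0;
    while (feature[node] != NA_INTEGER) {
      double x = X(r, feature[node] - 1);
      bool go_left = ISNAN(x) ? (bool)missing_left[node]
                              : (x < threshold[node]);
      node = (go_left ? left[node] : right[node]) - 1;
    }
    out[r] = value[node];
  }
  return out;
}
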