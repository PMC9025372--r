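#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Greedy multiclass CART with the entropy (information gain) criterion.
// Gains are reported in bits so per-node contributions can be aggregated
// directly into Monte Carlo feature selection importance scores.
// Split semantics: x <= threshold goes to the left child; thresholds are
// midpoints between consecutive distinct training values, so training
// samples never sit exactly on a boundary unless values coincide.

namespace {

double entropy_bits(const std::vector<int>& cnt, int n) {
  if (n <= 0) return 0.0;
  double h = 0.0;
  for (size_t k = 0; k < cnt.size(); ++k) {
    if (cnt[k] > 0) {
      double p = double(cnt[k]) / double(n);
      h -= p * std::log2(p);
    }
  }
  return h;
}

struct NodeRec {
  int feature;       // 0-based split feature, -1 for a leaf
  double threshold;
  int left, right;   // 0-based node ids, -1 for none
  int n;
  int pred;          // 0-based majority class (ties -> lowest index)
  double gain;       // information gain in bits (0 for leaves)
  std::vector<int> counts;
};

struct Builder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int n_classes, max_depth, min_split;
  std::vector<NodeRec> nodes;

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int K,
          int max_depth_, int min_split_)
    : X(X_), y(y_), n_classes(K), max_depth(max_depth_),
      min_split(min_split_) {}

  int build(std::vector<int>& rows, int depth) {
    NodeRec nd;
    nd.feature = -1; nd.threshold = NA_REAL; nd.left = -1; nd.right = -1;
    nd.n = (int)rows.size();
    nd.gain = 0.0;
    nd.counts.assign(n_classes, 0);
    for (int r : rows) nd.counts[y[r]]++;
    nd.pred = 0;
    for (int k = 1; k < n_classes; ++k)
      if (nd.counts[k] > nd.counts[nd.pred]) nd.pred = k;

    double h_parent = entropy_bits(nd.counts, nd.n);
    bool can_split = nd.n >= min_split && h_parent > 0.0 &&
                     (max_depth < 0 || depth < max_depth);

    int best_f = -1;
    double best_thr = 0.0, best_gain = 1e-12;
    if (can_split) {
      std::vector<int> idx;
      std::vector<int> lcnt(n_classes), rcnt(n_classes);
      for (int f = 0; f < X.ncol(); ++f) {
        idx = rows;
        NumericMatrix::ConstColumn col = X(_, f);
        std::sort(idx.begin(), idx.end(), [&](int a, int b) {
          return col[a] < col[b] || (col[a] == col[b] && a < b);
        });
        std::fill(lcnt.begin(), lcnt.end(), 0);
        int nl = 0;
        for (int i = 0; i + 1 < nd.n; ++i) {
          lcnt[y[idx[i]]]++; nl++;
          if (col[idx[i]] == col[idx[i + 1]]) continue;
          int nr = nd.n - nl;
          for (int k = 0; k < n_classes; ++k) rcnt[k] = nd.counts[k] - lcnt[k];
          double gain = h_parent
            - (double(nl) / nd.n) * entropy_bits(lcnt, nl)
            - (double(nr) / nd.n) * entropy_bits(rcnt, nr);
          if (gain > best_gain) {
            best_gain = gain;
            best_f = f;
            // midpoint written to avoid overflow on extreme values
            best_thr = col[idx[i]] / 2.0 + col[idx[i + 1]] / 2.0;
          }
        }
      }
    }

    int my_id = (int)nodes.size();
    nodes.push_back(nd);
    if (best_f >= 0) {
      std::vector<int> lrows, rrows;
      lrows.reserve(nd.n); rrows.reserve(nd.n);
      NumericMatrix::ConstColumn col = X(_, best_f);
      for (int r : rows) {
        if (col[r] <= best_thr) lrows.push_back(r); else rrows.push_back(r);
      }
      nodes[my_id].feature = best_f;
      nodes[my_id].threshold = best_thr;
      nodes[my_id].gain = best_gain;
      int lid = build(lrows, depth + 1);
      int rid = build(rrows, depth + 1);
      nodes[my_id].left = lid;
      nodes[my_id].right = rid;
    }
    return my_id;
  }
};

} // namespace

// [[Rcpp::export]]
List cart_fit_cpp(NumericMatrix X, IntegerVector y, int n_classes,
                  int max_depth, int min_split) {
  int n = X.nrow();
  if (n == 0) stop("cannot fit a tree on zero samples");
  Builder b(X, y, n_classes, max_depth, min_split);
  std::vector<int> rows(n);
  for (int i = 0; i < n; ++i) rows[i] = i;
  b.build(rows, 0);

  int m = (int)b.nodes.size();
  IntegerVector feature(m), left(m), right(m), nn(m), pred(m);
  NumericVector threshold(m), gain(m);
  IntegerMatrix counts(m, n_classes);
  for (int i = 0; i < m; ++i) {
    const NodeRec& nd = b.nodes[i];
    feature[i] = nd.feature;
    threshold[i] = nd.threshold;
    left[i] = nd.left;
    right[i] = nd.right;
    nn[i] = nd.n;
    pred[i] = nd.pred;
    gain[i] = nd.gain;
    for (int k = 0; k < n_classes; ++k) counts(i, k) = nd.counts[k];
  }
  return List::create(
    _["feature"] = feature, _["threshold"] = threshold,
    _["left"] = left, _["right"] = right, _["n"] = nn,
    _["pred"] = pred, _["gain"] = gain, _["counts"] = counts);
}

// [[Rcpp::export]]
IntegerVector cart_predict_cpp(IntegerVector feature, NumericVector threshold,
                               IntegerVector left, IntegerVector right,
                               IntegerVector pred, NumericMatrix X) {
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    }
    out[i] = pred[node];
  }
  return out;
}
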