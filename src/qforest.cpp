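// Quantile regression forest: bagged regression trees whose leaves retain
// the (in-bag) training targets, enabling conditional quantile prediction by
// pooling leaf targets across trees. Split rules: "variance" (exhaustive
// best threshold among mtry features) and extratrees-style random thresholds
// drawn uniformly between the feature's min and max within the node, with
// the best of mtry candidates chosen by variance reduction. Permutation
// importance is computed on out-of-bag rows. All randomness comes from the
// R RNG, so forests are reproducible via set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;       // -1: leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  int leaf_start = -1, leaf_len = 0;
  double leaf_mean = 0.0;
};

struct TreeBuilder {
  const NumericMatrix& X;
  const NumericVector& y;
  int mtry, min_node;
  bool extratrees;
  std::vector<Node> nodes;
  std::vector<double> pool;

  TreeBuilder(const NumericMatrix& X_, const NumericVector& y_, int mtry_,
              int min_node_, bool extra_)
      : X(X_), y(y_), mtry(mtry_), min_node(min_node_), extratrees(extra_) {}

  int make_leaf(const std::vector<int>& idx) {
    Node nd;
    nd.leaf_start = (int)pool.size();
    nd.leaf_len = (int)idx.size();
    double s = 0.0;
    for (int i : idx) { pool.push_back(y[i]); s += y[i]; }
    nd.leaf_mean = s / idx.size();
    nodes.push_back(nd);
    return (int)nodes.size() - 1;
  }

  int build(std::vector<int>& idx) {
    const int m = (int)idx.size();
    double s = 0.0, s2 = 0.0;
    for (int i : idx) { s += y[i]; s2 += y[i] * y[i]; }
    double sse = s2 - s * s / m;
    if (m < 2 * min_node || m < 2 || sse <= 1e-12) return make_leaf(idx);

    const int p = X.ncol();
    // sample mtry features without replacement
    std::vector<int> feats(p);
    for (int f = 0; f < p; ++f) feats[f] = f;
    for (int f = 0; f < mtry; ++f) {
      int j = f + (int)(unif_rand() * (p - f));
      if (j >= p) j = p - 1;
      std::swap(feats[f], feats[j]);
    }

    int best_f = -1;
    double best_thr = 0.0, best_score = -1.0;
    for (int fi = 0; fi < mtry; ++fi) {
      int f = feats[fi];
      double lo = X(idx[0], f), hi = lo;
      for (int i : idx) {
        double v = X(i, f);
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      if (hi <= lo) continue;
      if (extratrees) {
        double thr = lo + unif_rand() * (hi - lo);
        if (thr >= hi) thr = std::nextafter(hi, lo);
        double sl = 0.0, sl2 = 0.0; int nl = 0;
        for (int i : idx) {
          if (X(i, f) <= thr) { sl += y[i]; sl2 += y[i] * y[i]; ++nl; }
        }
        int nr = m - nl;
        if (nl < min_node || nr < min_node) continue;
        double sr = s - sl, sr2 = s2 - sl2;
        double score = sse - (sl2 - sl * sl / nl) - (sr2 - sr * sr / nr);
        if (score > best_score) { best_score = score; best_f = f; best_thr = thr; }
      } else {
        // exhaustive scan over sorted unique thresholds
        std::vector<std::pair<double, double>> xv(m);
        for (int j = 0; j < m; ++j) xv[j] = {X(idx[j], f), y[idx[j]]};
        std::sort(xv.begin(), xv.end());
        double sl = 0.0, sl2 = 0.0;
        for (int j = 0; j < m - 1; ++j) {
          sl += xv[j].second; sl2 += xv[j].second * xv[j].second;
          if (xv[j].first == xv[j + 1].first) continue;
          int nl = j + 1, nr = m - nl;
          if (nl < min_node || nr < min_node) continue;
          double sr = s - sl, sr2 = s2 - sl2;
          double score = sse - (sl2 - sl * sl / nl) - (sr2 - sr * sr / nr);
          if (score > best_score) {
            best_score = score;
            best_f = f;
            best_thr = 0.5 * (xv[j].first + xv[j + 1].first);
          }
        }
      }
    }
    if (best_f < 0) return make_leaf(idx);

    std::vector<int> li, ri;
    for (int i : idx) (X(i, best_f) <= best_thr ? li : ri).push_back(i);
    if ((int)li.size() < min_node || (int)ri.size() < min_node)
      return make_leaf(idx);

    int me = (int)nodes.size();
    nodes.push_back(Node());
    nodes[me].feature = best_f;
    nodes[me].threshold = best_thr;
    int l = build(li);
    int r = build(ri);
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }
};

struct Forest {
  std::vector<int> tree_offset;  // n_trees + 1
  std::vector<int> feature, left, right, leaf_start, leaf_len;
  std::vector<double> threshold, leaf_mean, pool;
  std::vector<int> pool_offset;  // per tree offset into pool
};

int descend(const Forest& fo, int t, const double* xrow, int stride_rows,
            int row) {
  int nd = fo.tree_offset[t];
  while (fo.feature[nd] >= 0) {
    double v = xrow[row + (size_t)stride_rows * fo.feature[nd]];
    nd = (v <= fo.threshold[nd]) ? fo.left[nd] : fo.right[nd];
  }
  return nd;
}

Forest unpack(const List& model) {
  Forest fo;
  fo.tree_offset = as<std::vector<int>>(model["tree_offset"]);
  fo.feature = as<std::vector<int>>(model["feature"]);
  fo.threshold = as<std::vector<double>>(model["threshold"]);
  fo.left = as<std::vector<int>>(model["left"]);
  fo.right = as<std::vector<int>>(model["right"]);
  fo.leaf_start = as<std::vector<int>>(model["leaf_start"]);
  fo.leaf_len = as<std::vector<int>>(model["leaf_len"]);
  fo.leaf_mean = as<std::vector<double>>(model["leaf_mean"]);
  fo.pool = as<std::vector<double>>(model["pool"]);
  return fo;
}

double tree_predict(const Forest& fo, int t, const NumericMatrix& X, int row) {
  int nd = fo.tree_offset[t];
  while (fo.feature[nd] >= 0) {
    double v = X(row, fo.feature[nd]);
    nd = (v <= fo.threshold[nd]) ? fo.left[nd] : fo.right[nd];
  }
  return fo.leaf_mean[nd];
}

}  // namespace

// [[Rcpp::export(name = ".qf_train_cpp")]]
List qf_train_cpp(const NumericMatrix& X, const NumericVector& y, int n_trees,
                  int mtry, int min_node, bool extratrees, bool bag,
                  bool importance) {
  const int n = X.nrow(), p = X.ncol();
  Forest fo;
  fo.tree_offset.push_back(0);
  std::vector<std::vector<int>> oob_rows(n_trees);
  std::vector<double> imp(p, 0.0);
  int imp_trees = 0;

  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx;
    std::vector<int> inbag(n, 0);
    if (bag) {
      idx.reserve(n);
      for (int i = 0; i < n; ++i) {
        int j = (int)(unif_rand() * n);
        if (j == n) j = n - 1;
        idx.push_back(j);
        ++inbag[j];
      }
    } else {
      idx.resize(n);
      for (int i = 0; i < n; ++i) { idx[i] = i; inbag[i] = 1; }
    }
    TreeBuilder tb(X, y, std::min(mtry, p), min_node, extratrees);
    tb.build(idx);
    int base = fo.tree_offset.back();
    int pool_base = (int)fo.pool.size();
    for (const Node& nd : tb.nodes) {
      fo.feature.push_back(nd.feature);
      fo.threshold.push_back(nd.threshold);
      fo.left.push_back(nd.left >= 0 ? nd.left + base : -1);
      fo.right.push_back(nd.right >= 0 ? nd.right + base : -1);
      fo.leaf_start.push_back(nd.leaf_start >= 0 ? nd.leaf_start + pool_base : -1);
      fo.leaf_len.push_back(nd.leaf_len);
      fo.leaf_mean.push_back(nd.leaf_mean);
    }
    fo.pool.insert(fo.pool.end(), tb.pool.begin(), tb.pool.end());
    fo.tree_offset.push_back(base + (int)tb.nodes.size());
    if (bag)
      for (int i = 0; i < n; ++i)
        if (inbag[i] == 0) oob_rows[t].push_back(i);
  }

  if (importance && bag) {
    for (int t = 0; t < n_trees; ++t) {
      const std::vector<int>& oob = oob_rows[t];
      const int m = (int)oob.size();
      if (m < 2) continue;
      std::vector<double> pred(m);
      double err0 = 0.0;
      for (int j = 0; j < m; ++j) {
        pred[j] = tree_predict(fo, t, X, oob[j]);
        double d = pred[j] - y[oob[j]];
        err0 += d * d;
      }
      err0 /= m;
      // permute each feature among OOB rows
      NumericMatrix Xp(m, X.ncol());
      for (int j = 0; j < m; ++j)
        for (int f = 0; f < p; ++f) Xp(j, f) = X(oob[j], f);
      for (int f = 0; f < p; ++f) {
        std::vector<double> orig(m);
        for (int j = 0; j < m; ++j) orig[j] = Xp(j, f);
        // Fisher-Yates with R RNG
        std::vector<double> perm = orig;
        for (int j = m - 1; j > 0; --j) {
          int u = (int)(unif_rand() * (j + 1));
          if (u > j) u = j;
          std::swap(perm[j], perm[u]);
        }
        for (int j = 0; j < m; ++j) Xp(j, f) = perm[j];
        double errf = 0.0;
        for (int j = 0; j < m; ++j) {
          double d = tree_predict(fo, t, Xp, j) - y[oob[j]];
          errf += d * d;
        }
        errf /= m;
        imp[f] += errf - err0;
        for (int j = 0; j < m; ++j) Xp(j, f) = orig[j];
      }
      ++imp_trees;
    }
    if (imp_trees > 0)
      for (int f = 0; f < p; ++f) imp[f] /= imp_trees;
  }

  return List::create(
      _["n_trees"] = n_trees, _["tree_offset"] = wrap(fo.tree_offset),
      _["feature"] = wrap(fo.feature), _["threshold"] = wrap(fo.threshold),
      _["left"] = wrap(fo.left), _["right"] = wrap(fo.right),
      _["leaf_start"] = wrap(fo.leaf_start), _["leaf_len"] = wrap(fo.leaf_len),
      _["leaf_mean"] = wrap(fo.leaf_mean), _["pool"] = wrap(fo.pool),
      _["importance"] = (importance && bag) ? wrap(imp) : R_NilValue);
}

// [[Rcpp::export(name = ".qf_predict_mean_cpp")]]
NumericVector qf_predict_mean_cpp(const List& model, const NumericMatrix& X) {
  Forest fo = unpack(model);
  const int n_trees = (int)fo.tree_offset.size() - 1;
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int t = 0; t < n_trees; ++t) s += tree_predict(fo, t, X, i);
    out[i] = s / n_trees;
  }
  return out;
}

// [[Rcpp::export(name = ".qf_predict_quantiles_cpp")]]
NumericMatrix qf_predict_quantiles_cpp(const List& model,
                                       const NumericMatrix& X,
                                       const NumericVector& taus) {
  Forest fo = unpack(model);
  const int n_trees = (int)fo.tree_offset.size() - 1;
  const int n = X.nrow(), q = taus.size();
  NumericMatrix out(n, q);
  std::vector<std::pair<double, double>> vw;  // (target value, weight)
  for (int i = 0; i < n; ++i) {
    vw.clear();
    for (int t = 0; t < n_trees; ++t) {
      int nd = fo.tree_offset[t];
      while (fo.feature[nd] >= 0) {
        double v = X(i, fo.feature[nd]);
        nd = (v <= fo.threshold[nd]) ? fo.left[nd] : fo.right[nd];
      }
      double w = 1.0 / ((double)fo.leaf_len[nd] * n_trees);
      for (int j = 0; j < fo.leaf_len[nd]; ++j)
        vw.push_back({fo.pool[fo.leaf_start[nd] + j], w});
    }
    std::sort(vw.begin(), vw.end());
    for (int k = 0; k < q; ++k) {
      double cum = 0.0, val = vw.back().first;
      for (const auto& pr : vw) {
        cum += pr.second;
        if (cum >= taus[k] - 1e-12) { val = pr.first; break; }
      }
      out(i, k) = val;
    }
  }
  return out;
}
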