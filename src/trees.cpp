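// CART tree engine: weighted classification/regression trees, prediction,
// and exact path-dependent Shapley attribution for tree ensembles.
//
// Trees are flat arrays: feature[i] == -1 marks a leaf; interior nodes send
// x[feature] <= threshold to `left`. `cover` is the summed training weight
// reaching each node (the distribution used by path-dependent attribution).

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct TreeBuf {
  std::vector<int> feature, left, right;
  std::vector<double> threshold, cover;
  std::vector<std::vector<double>> value; // per node, length n_out
};

static double node_impurity_gini(const std::vector<double> &cw, double W) {
  double g = 1.0;
  for (double c : cw) g -= (c / W) * (c / W);
  return g;
}

// recursive best-first CART builder
static int build_node(TreeBuf &T, const NumericMatrix &X,
                      const NumericVector &y, const IntegerVector &ycls,
                      int K, const NumericVector &w,
                      std::vector<int> &idx, int depth,
                      int max_depth, int min_leaf, int mtry,
                      std::mt19937 &rng) {
  const int n = idx.size();
  const int p = X.ncol();
  double W = 0.0;
  for (int i : idx) W += w[i];

  // node value
  std::vector<double> val;
  if (K > 0) {
    val.assign(K, 0.0);
    for (int i : idx) val[ycls[i]] += w[i];
    for (int k = 0; k < K; ++k) val[k] /= W;
  } else {
    double s = 0.0;
    for (int i : idx) s += w[i] * y[i];
    val.assign(1, s / W);
  }

  const int me = T.feature.size();
  T.feature.push_back(-1);
  T.threshold.push_back(0.0);
  T.left.push_back(-1);
  T.right.push_back(-1);
  T.cover.push_back(W);
  T.value.push_back(val);

  // stopping rules
  bool pure;
  if (K > 0) {
    pure = true;
    int first = ycls[idx[0]];
    for (int i : idx) if (ycls[i] != first) { pure = false; break; }
  } else {
    pure = true;
    double first = y[idx[0]];
    for (int i : idx) if (y[i] != first) { pure = false; break; }
  }
  if (pure || depth >= max_depth || n < 2 * min_leaf) return me;

  // candidate features (without replacement)
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int m_try = std::min(mtry, p);
  for (int j = 0; j < m_try; ++j) {
    std::uniform_int_distribution<int> pick(j, p - 1);
    std::swap(feats[j], feats[pick(rng)]);
  }

  int best_f = -1, best_pos = -1;
  double best_gain = 1e-12, best_thr = 0.0;
  std::vector<int> ord(n);
  std::vector<double> xv(n);

  // parent impurity contribution
  double parent_imp;
  std::vector<double> cw_all;
  double sum_wy = 0.0, sum_wyy = 0.0;
  if (K > 0) {
    cw_all.assign(K, 0.0);
    for (int i : idx) cw_all[ycls[i]] += w[i];
    parent_imp = W * node_impurity_gini(cw_all, W);
  } else {
    for (int i : idx) { sum_wy += w[i] * y[i]; sum_wyy += w[i] * y[i] * y[i]; }
    parent_imp = sum_wyy - sum_wy * sum_wy / W;
  }

  std::vector<int> best_ord;
  for (int jj = 0; jj < m_try; ++jj) {
    const int f = feats[jj];
    for (int i = 0; i < n; ++i) xv[i] = X(idx[i], f);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return xv[a] < xv[b]; });
    if (xv[ord[0]] == xv[ord[n - 1]]) continue; // constant in node

    if (K > 0) {
      std::vector<double> cwl(K, 0.0);
      double Wl = 0.0;
      for (int s = 0; s < n - 1; ++s) {
        const int i = idx[ord[s]];
        Wl += w[i];
        cwl[ycls[i]] += w[i];
        if (xv[ord[s]] == xv[ord[s + 1]]) continue;
        if (s + 1 < min_leaf || n - s - 1 < min_leaf) continue;
        double Wr = W - Wl;
        double gl = 1.0, gr = 1.0;
        for (int k = 0; k < K; ++k) {
          gl -= (cwl[k] / Wl) * (cwl[k] / Wl);
          double cr = cw_all[k] - cwl[k];
          gr -= (cr / Wr) * (cr / Wr);
        }
        double gain = parent_imp - (Wl * gl + Wr * gr);
        if (gain > best_gain) {
          best_gain = gain; best_f = f; best_pos = s;
          best_thr = (xv[ord[s]] + xv[ord[s + 1]]) / 2.0;
          best_ord = ord;
        }
      }
    } else {
      double Wl = 0.0, swl = 0.0, swyl = 0.0;
      for (int s = 0; s < n - 1; ++s) {
        const int i = idx[ord[s]];
        Wl += w[i]; swl += w[i] * y[i]; swyl += w[i] * y[i] * y[i];
        if (xv[ord[s]] == xv[ord[s + 1]]) continue;
        if (s + 1 < min_leaf || n - s - 1 < min_leaf) continue;
        double Wr = W - Wl;
        double sse_l = swyl - swl * swl / Wl;
        double sse_r = (sum_wyy - swyl) - (sum_wy - swl) * (sum_wy - swl) / Wr;
        double gain = parent_imp - (sse_l + sse_r);
        if (gain > best_gain) {
          best_gain = gain; best_f = f; best_pos = s;
          best_thr = (xv[ord[s]] + xv[ord[s + 1]]) / 2.0;
          best_ord = ord;
        }
      }
    }
  }

  if (best_f < 0) return me; // no improving split among candidates

  std::vector<int> idx_l, idx_r;
  idx_l.reserve(best_pos + 1);
  idx_r.reserve(n - best_pos - 1);
  for (int s = 0; s < n; ++s) {
    int i = idx[best_ord[s]];
    if (s <= best_pos) idx_l.push_back(i); else idx_r.push_back(i);
  }
  T.feature[me] = best_f;
  T.threshold[me] = best_thr;
  int lchild = build_node(T, X, y, ycls, K, w, idx_l, depth + 1,
                          max_depth, min_leaf, mtry, rng);
  T.left[me] = lchild;
  int rchild = build_node(T, X, y, ycls, K, w, idx_r, depth + 1,
                          max_depth, min_leaf, mtry, rng);
  T.right[me] = rchild;
  return me;
}

// [[Rcpp::export]]
List cpp_build_tree(NumericMatrix X, NumericVector y, IntegerVector ycls,
                    int K, NumericVector w, int max_depth, int min_leaf,
                    int mtry, int seed) {
  std::mt19937 rng(static_cast<unsigned>(seed));
  TreeBuf T;
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  if (max_depth <= 0) max_depth = 30;
  build_node(T, X, y, ycls, K, w, idx, 0, max_depth, min_leaf, mtry, rng);

  const int nn = T.feature.size();
  const int n_out = T.value[0].size();
  NumericMatrix val(nn, n_out);
  for (int i = 0; i < nn; ++i)
    for (int k = 0; k < n_out; ++k) val(i, k) = T.value[i][k];
  return List::create(
    _["feature"] = IntegerVector(T.feature.begin(), T.feature.end()),
    _["threshold"] = NumericVector(T.threshold.begin(), T.threshold.end()),
    _["left"] = IntegerVector(T.left.begin(), T.left.end()),
    _["right"] = IntegerVector(T.right.begin(), T.right.end()),
    _["cover"] = NumericVector(T.cover.begin(), T.cover.end()),
    _["value"] = val);
}

static int descend(const IntegerVector &feature, const NumericVector &threshold,
                   const IntegerVector &left, const IntegerVector &right,
                   const NumericMatrix &X, int row) {
  int node = 0;
  while (feature[node] >= 0) {
    node = (X(row, feature[node]) <= threshold[node]) ? left[node] : right[node];
  }
  return node;
}

// [[Rcpp::export]]
NumericMatrix cpp_predict_tree(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"], right = tree["right"];
  NumericVector threshold = tree["threshold"];
  NumericMatrix value = tree["value"];
  const int n = X.nrow(), n_out = value.ncol();
  NumericMatrix out(n, n_out);
  for (int i = 0; i < n; ++i) {
    int leaf = descend(feature, threshold, left, right, X, i);
    for (int k = 0; k < n_out; ++k) out(i, k) = value(leaf, k);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_leaf_index(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"], right = tree["right"];
  NumericVector threshold = tree["threshold"];
  const int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = descend(feature, threshold, left, right, X, i);
  return out;
}

// ---- exact path-dependent Shapley attribution ------------------------------

struct PathElement {
  int d;          // feature index entering the path (-1 for the root dummy)
  double z;       // fraction of "zero" (feature-absent) paths flowing through
  double o;       // fraction of "one" (feature-present) paths (0 or 1)
  double w;       // permutation weight
};

static void extend_path(std::vector<PathElement> &m, double pz, double po, int pi) {
  const int l = m.size();
  m.push_back({pi, pz, po, l == 0 ? 1.0 : 0.0});
  for (int i = l - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (i + 1) / static_cast<double>(l + 1);
    m[i].w = pz * m[i].w * (l - i) / static_cast<double>(l + 1);
  }
}

static void unwind_path(std::vector<PathElement> &m, int i) {
  const int l = m.size() - 1;
  const double o = m[i].o, z = m[i].z;
  double nx = m[l].w;
  for (int j = l - 1; j >= 0; --j) {
    if (o != 0) {
      const double tmp = m[j].w;
      m[j].w = nx * (l + 1) / static_cast<double>((j + 1) * o);
      nx = tmp - m[j].w * z * (l - j) / static_cast<double>(l + 1);
    } else {
      m[j].w = m[j].w * (l + 1) / static_cast<double>(z * (l - j));
    }
  }
  // shift the feature/fraction fields only: the recomputed weights already
  // occupy positions 0..l-1 for the shortened path
  for (int j = i; j < l; ++j) {
    m[j].d = m[j + 1].d;
    m[j].z = m[j + 1].z;
    m[j].o = m[j + 1].o;
  }
  m.pop_back();
}

static double unwound_sum(const std::vector<PathElement> &m, int i) {
  const int l = m.size() - 1;
  const double o = m[i].o, z = m[i].z;
  double total = 0.0, nx = m[l].w;
  if (o != 0) {
    for (int j = l - 1; j >= 0; --j) {
      const double tmp = nx / static_cast<double>((j + 1) * o);
      total += tmp;
      nx = m[j].w - tmp * z * (l - j);
    }
  } else {
    for (int j = l - 1; j >= 0; --j) {
      total += m[j].w / (z * static_cast<double>(l - j));
    }
  }
  return total * (l + 1);
}

struct ShapCtx {
  const IntegerVector *feature, *left, *right;
  const NumericVector *threshold, *cover;
  const NumericMatrix *value;
  const NumericMatrix *X;
  int row, out_dim;
  double *phi;
};

static void shap_recurse(ShapCtx &C, int node, std::vector<PathElement> m,
                         double pz, double po, int pi) {
  extend_path(m, pz, po, pi);
  const IntegerVector &feature = *C.feature;
  if (feature[node] < 0) { // leaf
    const double leaf_val = (*C.value)(node, C.out_dim);
    for (int i = 1; i < static_cast<int>(m.size()); ++i) {
      const double w = unwound_sum(m, i);
      C.phi[m[i].d] += w * (m[i].o - m[i].z) * leaf_val;
    }
    return;
  }
  const int f = feature[node];
  const int l = (*C.left)[node], r = (*C.right)[node];
  const bool go_left = (*C.X)(C.row, f) <= (*C.threshold)[node];
  const int hot = go_left ? l : r, cold = go_left ? r : l;
  double iz = 1.0, io = 1.0;
  // previous occurrence of this feature on the path
  int k = -1;
  for (int i = 0; i < static_cast<int>(m.size()); ++i)
    if (m[i].d == f) { k = i; break; }
  if (k >= 0) {
    iz = m[k].z;
    io = m[k].o;
    unwind_path(m, k);
  }
  const double cn = (*C.cover)[node];
  shap_recurse(C, hot, m, iz * (*C.cover)[hot] / cn, io, f);
  shap_recurse(C, cold, m, iz * (*C.cover)[cold] / cn, 0.0, f);
}

// Shapley attributions of one tree, one output dimension, for every row of X.
// Returns an n x p matrix; the tree's base value (cover-weighted leaf mean)
// is in attribute "base".
// [[Rcpp::export]]
NumericMatrix cpp_tree_shap(List tree, NumericMatrix X, int out_dim) {
  IntegerVector feature = tree["feature"], left = tree["left"], right = tree["right"];
  NumericVector threshold = tree["threshold"], cover = tree["cover"];
  NumericMatrix value = tree["value"];
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix phi(n, p);

  // base value: cover-weighted mean over leaves
  double base = 0.0;
  for (int i = 0; i < feature.size(); ++i)
    if (feature[i] < 0) base += cover[i] / cover[0] * value(i, out_dim);

  ShapCtx C;
  C.feature = &feature; C.left = &left; C.right = &right;
  C.threshold = &threshold; C.cover = &cover; C.value = &value;
  C.X = &X; C.out_dim = out_dim;
  for (int i = 0; i < n; ++i) {
    C.row = i;
    std::vector<double> ph(p, 0.0);
    C.phi = ph.data();
    std::vector<PathElement> m;
    if (feature[0] < 0) {
      // single-leaf tree: nothing to attribute
    } else {
      shap_recurse(C, 0, m, 1.0, 1.0, -1);
    }
    for (int j = 0; j < p; ++j) phi(i, j) = ph[j];
  }
  phi.attr("base") = base;
  return phi;
}
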