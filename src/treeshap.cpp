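// Exact path-dependent TreeSHAP for tree ensembles.
//
// Trees are passed as parallel arrays (0-based children, feature = -1 at
// leaves). Covers are training-sample node counts; the expected value of a
// tree is its cover-weighted leaf mean, and per-instance attributions follow
// the polynomial-time recursion over feature subsets encoded as weighted
// decision paths.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct PathEl {
  int d;        // feature index of the split that created this element
  double z;     // fraction of paths that flow through when the feature is unknown
  double o;     // 1 if the instance's value follows this branch, else 0
  double w;     // permutation weight
};

static void extend_path(std::vector<PathEl>& p, double pz, double po, int pd) {
  int depth = (int)p.size();
  p.push_back({pd, pz, po, depth == 0 ? 1.0 : 0.0});
  for (int i = depth - 1; i >= 0; --i) {
    p[i + 1].w += po * p[i].w * (i + 1) / double(depth + 1);
    p[i].w = pz * p[i].w * (depth - i) / double(depth + 1);
  }
}

static void unwind_path(std::vector<PathEl>& p, int ud, int pi) {
  double o = p[pi].o, z = p[pi].z;
  double n = p[ud].w;
  for (int i = ud - 1; i >= 0; --i) {
    if (o != 0.0) {
      double t = p[i].w;
      p[i].w = n * (ud + 1) / double((i + 1) * o);
      n = t - p[i].w * z * (ud - i) / double(ud + 1);
    } else {
      p[i].w = p[i].w * (ud + 1) / (z * double(ud - i));
    }
  }
  for (int i = pi; i < ud; ++i) {
    p[i].d = p[i + 1].d;
    p[i].z = p[i + 1].z;
    p[i].o = p[i + 1].o;
  }
  p.resize(ud);
}

static double unwound_sum(const std::vector<PathEl>& p, int ud, int pi) {
  double o = p[pi].o, z = p[pi].z, total = 0.0;
  double n = p[ud].w;
  for (int i = ud - 1; i >= 0; --i) {
    if (o != 0.0) {
      double t = n * (ud + 1) / double((i + 1) * o);
      total += t;
      n = p[i].w - t * z * (ud - i) / double(ud + 1);
    } else {
      total += p[i].w / (z * double(ud - i) / double(ud + 1));
    }
  }
  return total;
}

struct Tree {
  const int *left, *right, *feature;
  const double *thresh, *value, *cover;
  bool strict_less;
};

static void shap_recurse(const Tree& tr, const double* x,
                         std::vector<PathEl> path, int node,
                         double pz, double po, int pd,
                         double* phi, double scale) {
  extend_path(path, pz, po, pd);
  int ud = (int)path.size() - 1;
  int f = tr.feature[node];
  if (f < 0) {  // leaf
    for (int i = 1; i <= ud; ++i) {
      double w = unwound_sum(path, ud, i);
      phi[path[i].d] += w * (path[i].o - path[i].z) * tr.value[node] * scale;
    }
    return;
  }
  double xv = x[f];
  bool goleft = tr.strict_less ? (xv < tr.thresh[node]) : (xv <= tr.thresh[node]);
  int hot = goleft ? tr.left[node] : tr.right[node];
  int cold = goleft ? tr.right[node] : tr.left[node];
  double iz = 1.0, io = 1.0;
  int k = -1;
  for (int i = 1; i <= ud; ++i)
    if (path[i].d == f) { k = i; break; }
  if (k >= 0) {
    iz = path[k].z;
    io = path[k].o;
    unwind_path(path, ud, k);
  }
  double rj = tr.cover[node];
  shap_recurse(tr, x, path, hot, iz * tr.cover[hot] / rj, io, f, phi, scale);
  shap_recurse(tr, x, path, cold, iz * tr.cover[cold] / rj, 0.0, f, phi, scale);
}

static Tree tree_view(const List& tl) {
  Tree tr;
  tr.left = INTEGER(tl["left"]);
  tr.right = INTEGER(tl["right"]);
  tr.feature = INTEGER(tl["feature"]);
  tr.thresh = REAL(tl["threshold"]);
  tr.value = REAL(tl["value"]);
  tr.cover = REAL(tl["cover"]);
  tr.strict_less = as<bool>(tl["strict_less"]);
  return tr;
}

// cover-weighted expected value of one tree
static double tree_expectation(const Tree& tr, int node) {
  if (tr.feature[node] < 0) return tr.value[node];
  double cl = tr.cover[tr.left[node]], cr = tr.cover[tr.right[node]];
  return (cl * tree_expectation(tr, tr.left[node]) +
          cr * tree_expectation(tr, tr.right[node])) / (cl + cr);
}

// [[Rcpp::export(name = ".treeshap_cpp")]]
List treeshap_cpp(List trees, NumericMatrix X, double scale) {
  int n = X.nrow(), d = X.ncol(), T = trees.size();
  NumericMatrix phi(n, d);
  double base = 0.0;
  std::vector<Tree> tv(T);
  for (int t = 0; t < T; ++t) {
    tv[t] = tree_view(trees[t]);
    base += tree_expectation(tv[t], 0) * scale;
  }
  std::vector<double> xrow(d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) xrow[j] = X(i, j);
    double* phirow = new double[d]();
    for (int t = 0; t < T; ++t) {
      std::vector<PathEl> path;
      path.reserve(64);
      shap_recurse(tv[t], xrow.data(), path, 0, 1.0, 1.0, -1, phirow, scale);
    }
    for (int j = 0; j < d; ++j) phi(i, j) = phirow[j];
    delete[] phirow;
  }
  return List::create(Named("phi") = phi, Named("base_value") = base);
}

// Route rows of X down one tree, counting visits per node.
// [[Rcpp::export(name = ".tree_cover_cpp")]]
NumericVector tree_cover_cpp(IntegerVector left, IntegerVector right,
                             IntegerVector feature, NumericVector threshold,
                             NumericMatrix X, bool strict_less) {
  int nn = left.size();
  NumericVector cover(nn);
  for (int i = 0; i < X.nrow(); ++i) {
    int node = 0;
    while (true) {
      cover[node] += 1.0;
      int f = feature[node];
      if (f < 0) break;
      double xv = X(i, f);
      bool goleft = strict_less ? (xv < threshold[node]) : (xv <= threshold[node]);
      node = goleft ? left[node] : right[node];
    }
  }
  return cover;
}

// Ensemble prediction from the parsed trees (conversion self-check).
// [[Rcpp::export(name = ".tree_predict_cpp")]]
NumericVector tree_predict_cpp(List trees, NumericMatrix X, double scale,
                               double offset) {
  int n = X.nrow(), T = trees.size();
  NumericVector out(n, offset);
  for (int t = 0; t < T; ++t) {
    Tree tr = tree_view(trees[t]);
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (tr.feature[node] >= 0) {
        double xv = X(i, tr.feature[node]);
        bool goleft = tr.strict_less ? (xv < tr.thresh[node])
                                     : (xv <= tr.thresh[node]);
        node = goleft ? tr.left[node] : tr.right[node];
      }
      out[i] += tr.value[node] * scale;
    }
  }
  return out;
}

// Round doubles through float32, matching xgboost's internal precision.
// [[Rcpp::export(name = ".float32_round_cpp")]]
NumericMatrix float32_round_cpp(NumericMatrix X) {
  NumericMatrix out(X.nrow(), X.ncol());
  for (int j = 0; j < X.ncol(); ++j)
    for (int i = 0; i < X.nrow(); ++i)
      out(i, j) = (double)(float)X(i, j);
  return out;
}
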