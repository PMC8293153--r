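#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Immersion watershed, 6-connectivity.
//
// Voxels are processed in order of decreasing density (density peaks are the
// "mountain tops": the topographic analogy is inverted so each protein blob
// grows a basin from its local maximum). A voxel with no labelled neighbour
// starts a new basin; otherwise it joins the basin of its steepest (highest
// density) labelled neighbour. Ties in density are broken by linear index so
// the result is fully deterministic.
// ---------------------------------------------------------------------------

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// [[Rcpp::export]]
IntegerVector watershed_cpp(NumericVector dens, IntegerVector dim,
                            LogicalVector mask) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  if (dens.size() != n || mask.size() != n)
    stop("density/mask size does not match dimensions");

  std::vector<int> order;
  order.reserve(n);
  for (int i = 0; i < n; ++i)
    if (mask[i]) order.push_back(i);
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    if (dens[a] != dens[b]) return dens[a] > dens[b];
    return a < b;
  });

  IntegerVector labels(n, 0);
  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};
  int next_label = 0;

  for (size_t k = 0; k < order.size(); ++k) {
    const int i = order[k];
    const int z = i / (nx * ny);
    const int y = (i / nx) % ny;
    const int x = i % nx;
    int best = -1;
    double best_d = -std::numeric_limits<double>::infinity();
    for (int d = 0; d < 6; ++d) {
      const int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      const int j = lin(xx, yy, zz, nx, ny);
      if (labels[j] > 0 && dens[j] > best_d) {
        best_d = dens[j];
        best = j;
      }
    }
    labels[i] = (best < 0) ? ++next_label : labels[best];
  }
  return labels;
}

// ---------------------------------------------------------------------------
// Separable 3D Gaussian smoothing with reflected boundaries.
// ---------------------------------------------------------------------------

static void smooth_axis(std::vector<double> &v, std::vector<double> &out,
                        int nx, int ny, int nz, int axis,
                        const std::vector<double> &kern) {
  const int r = (int)kern.size() / 2;
  const int len = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double acc = 0.0;
        const int pos = (axis == 0) ? x : (axis == 1) ? y : z;
        for (int t = -r; t <= r; ++t) {
          int p = pos + t;
          if (p < 0) p = -p - 1;          // reflect
          if (p >= len) p = 2 * len - p - 1;
          int j;
          if (axis == 0) j = lin(p, y, z, nx, ny);
          else if (axis == 1) j = lin(x, p, z, nx, ny);
          else j = lin(x, y, p, nx, ny);
          acc += kern[t + r] * v[j];
        }
        out[lin(x, y, z, nx, ny)] = acc;
      }
}

// [[Rcpp::export]]
NumericVector gaussian_smooth_cpp(NumericVector grid, IntegerVector dim,
                                  double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  if (grid.size() != n) stop("grid size does not match dimensions");
  if (sigma <= 0) return clone(grid);

  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) {
    kern[t + r] = std::exp(-0.5 * (double)t * t / (sigma * sigma));
    s += kern[t + r];
  }
  for (double &k : kern) k /= s;

  std::vector<double> a(grid.begin(), grid.end()), b(n);
  smooth_axis(a, b, nx, ny, nz, 0, kern);
  smooth_axis(b, a, nx, ny, nz, 1, kern);
  smooth_axis(a, b, nx, ny, nz, 2, kern);
  return NumericVector(b.begin(), b.end());
}

// ---------------------------------------------------------------------------
// Random forest classifier (CART trees, gini impurity, bootstrap + mtry).
//
// Implemented here because no forest package ships with the target R stack;
// the fitness classifier is part of the method, so the forest is owned code.
// Trees are grown depth-first; leaves store the class-1 proportion of their
// bootstrap sample so predictions are averaged probabilities.
// ---------------------------------------------------------------------------

struct TreeBuf {
  std::vector<int> feat, left, right;
  std::vector<double> thr, pred;
};

static int grow_node(const NumericMatrix &X, const IntegerVector &y,
                     std::vector<int> &idx, int lo, int hi, int depth,
                     int mtry, int min_node, int max_depth, std::mt19937 &rng,
                     TreeBuf &T) {
  const int node = (int)T.feat.size();
  T.feat.push_back(-1);
  T.thr.push_back(0.0);
  T.left.push_back(-1);
  T.right.push_back(-1);

  const int m = hi - lo;
  int n1 = 0;
  for (int k = lo; k < hi; ++k) n1 += y[idx[k]];
  T.pred.push_back((double)n1 / m);
  if (m < 2 * min_node || depth >= max_depth || n1 == 0 || n1 == m)
    return node;

  const int d = X.ncol();
  std::vector<int> feats(d);
  for (int j = 0; j < d; ++j) feats[j] = j;
  // partial Fisher-Yates: first mtry entries are the candidate features
  for (int j = 0; j < mtry && j < d; ++j) {
    std::uniform_int_distribution<int> U(j, d - 1);
    std::swap(feats[j], feats[U(rng)]);
  }

  double best_gain = 0.0, best_thr = 0.0;
  int best_feat = -1;
  const double parent_imp = (double)n1 * (m - n1) / m;  // m * gini / 2

  std::vector<std::pair<double, int>> vals(m);
  for (int j = 0; j < mtry && j < d; ++j) {
    const int f = feats[j];
    for (int k = 0; k < m; ++k)
      vals[k] = std::make_pair(X(idx[lo + k], f), y[idx[lo + k]]);
    std::sort(vals.begin(), vals.end());
    int l1 = 0;
    for (int k = 0; k < m - 1; ++k) {
      l1 += vals[k].second;
      if (vals[k].first == vals[k + 1].first) continue;
      const int nl = k + 1, nr = m - nl, r1 = n1 - l1;
      if (nl < min_node || nr < min_node) continue;
      const double imp = (double)l1 * (nl - l1) / nl +
                         (double)r1 * (nr - r1) / nr;
      const double gain = parent_imp - imp;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_feat = f;
        best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
      }
    }
  }
  if (best_feat < 0) return node;

  int mid = lo;
  for (int k = lo; k < hi; ++k)
    if (X(idx[k], best_feat) <= best_thr) std::swap(idx[mid++], idx[k]);
  if (mid == lo || mid == hi) return node;

  T.feat[node] = best_feat;
  T.thr[node] = best_thr;
  T.left[node] = grow_node(X, y, idx, lo, mid, depth + 1, mtry, min_node,
                           max_depth, rng, T);
  T.right[node] = grow_node(X, y, idx, mid, hi, depth + 1, mtry, min_node,
                            max_depth, rng, T);
  return node;
}

// [[Rcpp::export]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                  int min_node, int max_depth, int seed) {
  const int n = X.nrow();
  if (y.size() != n) stop("X/y size mismatch");
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> boot(0, n - 1);
  List forest(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    TreeBuf T;
    grow_node(X, y, idx, 0, n, 0, mtry, min_node, max_depth, rng, T);
    forest[t] = List::create(
        _["feat"] = IntegerVector(T.feat.begin(), T.feat.end()),
        _["thr"] = NumericVector(T.thr.begin(), T.thr.end()),
        _["left"] = IntegerVector(T.left.begin(), T.left.end()),
        _["right"] = IntegerVector(T.right.begin(), T.right.end()),
        _["pred"] = NumericVector(T.pred.begin(), T.pred.end()));
  }
  return forest;
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  const int n = X.nrow(), ntree = forest.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < ntree; ++t) {
    List tree = forest[t];
    IntegerVector feat = tree["feat"], left = tree["left"],
                  right = tree["right"];
    NumericVector thr = tree["thr"], pred = tree["pred"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feat[node] >= 0)
        node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
      out[i] += pred[node];
    }
  }
  return out / (double)ntree;
}
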