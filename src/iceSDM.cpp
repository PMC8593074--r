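// Compiled kernels: stagewise Bernoulli gradient boosting with depth-limited
// regression trees, staged prediction, and multi-source shortest paths on a
// lon/lat grid (8-connected, great-circle edge lengths, land blocks paths).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <random>
#include <vector>

using namespace Rcpp;

static const double EARTH_RADIUS_KM = 6371.0;
static const double DEG_TO_RAD = M_PI / 180.0;

static inline double haversineKm(double lon1, double lat1,
                                 double lon2, double lat2) {
  double dlat = (lat2 - lat1) * DEG_TO_RAD;
  double dlon = (lon2 - lon1) * DEG_TO_RAD;
  double a = std::sin(dlat / 2) * std::sin(dlat / 2) +
             std::cos(lat1 * DEG_TO_RAD) * std::cos(lat2 * DEG_TO_RAD) *
                 std::sin(dlon / 2) * std::sin(dlon / 2);
  if (a > 1.0) a = 1.0;
  if (a < 0.0) a = 0.0;
  return 2.0 * EARTH_RADIUS_KM * std::asin(std::sqrt(a));
}

// ---------------------------------------------------------------------------
// Boosted regression trees
//
// Trees are stored as a numeric matrix, one row per node:
//   col 0: split variable (0-based; -1 for a leaf)
//   col 1: split value (x <= value goes left)
//   col 2: left child row (0-based)
//   col 3: right child row
//   col 4: 1 if missing values go left, 0 if right
//   col 5: leaf value (already multiplied by the learning rate)
// ---------------------------------------------------------------------------

struct BestSplit {
  double gain = -1.0;
  int var = -1;
  double value = 0.0;
  bool missLeft = true;
};

struct TreeNode {
  std::vector<int> rows;   // bagged row indices in this node
  int var = -1;
  double split = 0.0;
  int left = -1, right = -1;
  bool missLeft = true;
  double value = 0.0;
  BestSplit best;
  bool bestComputed = false;
};

// Least-squares best split of residual r over the node's rows.
static BestSplit findBestSplit(const NumericMatrix& X,
                               const std::vector<double>& r,
                               const std::vector<int>& rows,
                               int minNode) {
  BestSplit best;
  const int p = X.ncol();
  std::vector<std::pair<double, double>> xr;
  xr.reserve(rows.size());
  for (int j = 0; j < p; ++j) {
    xr.clear();
    double sAll = 0.0;
    int nMiss = 0;
    for (int idx : rows) {
      double x = X(idx, j);
      if (ISNAN(x)) {
        ++nMiss;
      } else {
        xr.emplace_back(x, r[idx]);
      }
      sAll += r[idx];
    }
    const int cnt = (int)xr.size();
    if (cnt < 2 * minNode) continue;
    std::sort(xr.begin(), xr.end());
    double sTot = 0.0;
    for (auto& pr : xr) sTot += pr.second;
    double baseSS = sTot * sTot / cnt;
    double sL = 0.0;
    for (int k = 1; k < cnt; ++k) {
      sL += xr[k - 1].second;
      if (k < minNode || cnt - k < minNode) continue;
      if (xr[k - 1].first == xr[k].first) continue;
      double sR = sTot - sL;
      double gain = sL * sL / k + sR * sR / (cnt - k) - baseSS;
      if (gain > best.gain) {
        best.gain = gain;
        best.var = j;
        best.value = 0.5 * (xr[k - 1].first + xr[k].first);
        best.missLeft = (k >= cnt - k);
      }
    }
    (void)nMiss;
    (void)sAll;
  }
  return best;
}

static inline int descend(const NumericMatrix& tree, const NumericMatrix& X,
                          int row) {
  int node = 0;
  while ((int)tree(node, 0) >= 0) {
    int j = (int)tree(node, 0);
    double x = X(row, j);
    bool goLeft;
    if (ISNAN(x)) {
      goLeft = tree(node, 4) > 0.5;
    } else {
      goLeft = (x <= tree(node, 1));
    }
    node = goLeft ? (int)tree(node, 2) : (int)tree(node, 3);
  }
  return node;
}

// [[Rcpp::export]]
List gbm_fit_cpp(NumericMatrix X, NumericVector y, int n_trees, int n_splits,
                 double shrinkage, double bag_fraction, int min_node,
                 int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 2) stop("need at least two rows");
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  ybar = std::min(1.0 - 1e-6, std::max(1e-6, ybar));
  const double F0 = std::log(ybar / (1.0 - ybar));
  std::vector<double> F(n, F0), r(n, 0.0), h(n, 0.0);

  std::mt19937 rng((unsigned)seed);
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  int nBag = std::max(2, (int)std::floor(bag_fraction * n));
  if (nBag > n) nBag = n;

  List trees(n_trees);
  NumericMatrix importance(p, n_trees);

  for (int t = 0; t < n_trees; ++t) {
    // bag: sample without replacement
    std::vector<int> bag;
    if (nBag == n) {
      bag = perm;
    } else {
      for (int i = 0; i < nBag; ++i) {
        std::uniform_int_distribution<int> unif(i, n - 1);
        std::swap(perm[i], perm[unif(rng)]);
      }
      bag.assign(perm.begin(), perm.begin() + nBag);
    }
    for (int idx : bag) {
      double pr = 1.0 / (1.0 + std::exp(-F[idx]));
      r[idx] = y[idx] - pr;
      h[idx] = std::max(pr * (1.0 - pr), 1e-10);
    }

    std::vector<TreeNode> nodes(1);
    nodes[0].rows = bag;
    int splits = 0;
    while (splits < n_splits) {
      int bestNode = -1;
      double bestGain = 0.0;
      for (size_t k = 0; k < nodes.size(); ++k) {
        if (nodes[k].var >= 0 || nodes[k].rows.empty()) continue;  // internal
        if (!nodes[k].bestComputed) {
          nodes[k].best = findBestSplit(X, r, nodes[k].rows, min_node);
          nodes[k].bestComputed = true;
        }
        if (nodes[k].best.gain > bestGain) {
          bestGain = nodes[k].best.gain;
          bestNode = (int)k;
        }
      }
      if (bestNode < 0) break;
      const BestSplit bs = nodes[bestNode].best;
      nodes[bestNode].var = bs.var;
      nodes[bestNode].split = bs.value;
      nodes[bestNode].missLeft = bs.missLeft;
      importance(bs.var, t) += bs.gain;
      TreeNode l, rr;
      for (int idx : nodes[bestNode].rows) {
        double x = X(idx, bs.var);
        bool goLeft = ISNAN(x) ? bs.missLeft : (x <= bs.value);
        (goLeft ? l.rows : rr.rows).push_back(idx);
      }
      nodes[bestNode].rows.clear();
      nodes[bestNode].rows.shrink_to_fit();
      const int li = (int)nodes.size();
      nodes.push_back(std::move(l));
      const int ri = (int)nodes.size();
      nodes.push_back(std::move(rr));
      nodes[bestNode].left = li;
      nodes[bestNode].right = ri;
      ++splits;
    }

    // leaf values: Newton step y - p over p(1-p), shrunk
    NumericMatrix tm(nodes.size(), 6);
    for (size_t k = 0; k < nodes.size(); ++k) {
      const TreeNode& nd = nodes[k];
      tm(k, 0) = nd.var;
      tm(k, 1) = nd.split;
      tm(k, 2) = nd.left;
      tm(k, 3) = nd.right;
      tm(k, 4) = nd.missLeft ? 1.0 : 0.0;
      if (nd.var < 0) {
        double sr = 0.0, sh = 0.0;
        for (int idx : nd.rows) {
          sr += r[idx];
          sh += h[idx];
        }
        double val = (sh > 1e-10) ? sr / sh : 0.0;
        if (val > 20.0) val = 20.0;
        if (val < -20.0) val = -20.0;
        tm(k, 5) = shrinkage * val;
      } else {
        tm(k, 5) = 0.0;
      }
    }
    // update F for all rows (in and out of bag)
    for (int i = 0; i < n; ++i) {
      int leaf = descend(tm, X, i);
      F[i] += tm(leaf, 5);
    }
    trees[t] = tm;
  }

  return List::create(Named("trees") = trees, Named("init") = F0,
                      Named("importance") = importance);
}

// Logit-scale predictions after the first `stages[k]` trees (stages sorted
// ascending). One column per stage.
// [[Rcpp::export]]
NumericMatrix gbm_predict_staged_cpp(NumericMatrix X, List trees, double init,
                                     IntegerVector stages) {
  const int n = X.nrow();
  const int nStages = stages.size();
  const int nTrees = trees.size();
  NumericMatrix out(n, nStages);
  std::vector<double> F(n, init);
  int s = 0;
  for (int t = 0; t <= nTrees; ++t) {
    while (s < nStages && stages[s] == t) {
      for (int i = 0; i < n; ++i) out(i, s) = F[i];
      ++s;
    }
    if (t == nTrees || s >= nStages) break;
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i) {
      int leaf = descend(tm, X, i);
      F[i] += tm(leaf, 5);
    }
  }
  // stages beyond nTrees: fill with final F
  for (; s < nStages; ++s)
    for (int i = 0; i < n; ++i) out(i, s) = F[i];
  return out;
}

// ---------------------------------------------------------------------------
// Multi-source Dijkstra on a lon/lat grid.
// open[i, j]  : TRUE if the cell is traversable (sea)
// source[i,j] : TRUE for zero-distance sources (must be open)
// lon, lat    : cell-centre coordinates (lon along rows, lat along columns)
// Returns km distances; NA for non-open cells; Inf for unreachable open
// cells.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix grid_distance_cpp(LogicalMatrix open, LogicalMatrix source,
                                NumericVector lon, NumericVector lat) {
  const int ni = open.nrow(), nj = open.ncol();
  if ((int)lon.size() != ni || (int)lat.size() != nj)
    stop("lon/lat lengths must match grid dimensions");
  NumericMatrix dist(ni, nj);
  std::vector<double> d(ni * nj, R_PosInf);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;

  for (int j = 0; j < nj; ++j)
    for (int i = 0; i < ni; ++i)
      if (source(i, j) && open(i, j)) {
        d[i + j * ni] = 0.0;
        pq.push(QE(0.0, i + j * ni));
      }

  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};

  while (!pq.empty()) {
    QE top = pq.top();
    pq.pop();
    int id = top.second;
    if (top.first > d[id]) continue;
    int i = id % ni, j = id / ni;
    for (int k = 0; k < 8; ++k) {
      int i2 = i + di[k], j2 = j + dj[k];
      if (i2 < 0 || i2 >= ni || j2 < 0 || j2 >= nj) continue;
      if (!open(i2, j2)) continue;
      double w = haversineKm(lon[i], lat[j], lon[i2], lat[j2]);
      double nd = top.first + w;
      int id2 = i2 + j2 * ni;
      if (nd < d[id2]) {
        d[id2] = nd;
        pq.push(QE(nd, id2));
      }
    }
  }

  for (int j = 0; j < nj; ++j)
    for (int i = 0; i < ni; ++i)
      dist(i, j) = open(i, j) ? d[i + j * ni] : NA_REAL;
  return dist;
}
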