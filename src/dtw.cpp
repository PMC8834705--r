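#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

// Banded dynamic time warping between two multivariate trajectories.
//
// Steps {(1,0),(0,1),(1,1)}, unweighted; local cost is the Euclidean
// distance between rows (or the geodesic quaternion angle when geodesic is
// true and the rows are unit quaternions).  Cells with
// |i*m/n - j| > w (1-based indices, slope-corrected diagonal) are forbidden.
// Ties in cumulative cost are broken towards the shorter path, so the
// reported path length is well defined: it is the minimum path length among
// minimum-cost paths.

static inline double local_cost(const double* a, const double* b, int d,
                                bool geodesic) {
  if (geodesic) {
    double dot = 0.0;
    for (int k = 0; k < d; ++k) dot += a[k] * b[k];
    if (dot < 0) dot = -dot;
    if (dot > 1.0) dot = 1.0;
    return 2.0 * std::acos(dot);
  }
  double s = 0.0;
  for (int k = 0; k < d; ++k) {
    double diff = a[k] - b[k];
    s += diff * diff;
  }
  return std::sqrt(s);
}

// core DP on column-major copies of the trajectories (n x d, m x d)
static void dtw_core(const double* a, const double* b, int n, int m, int d,
                     double window_fraction, bool geodesic,
                     double* out_cost, double* out_len, bool* widened) {
  const double INF = std::numeric_limits<double>::infinity();
  int w = (int)std::ceil(window_fraction * (double)std::max(n, m));
  // minimum half-width that keeps the slope-corrected diagonal connected:
  // for m <= n the rounded diagonal deviates by < 1; for m > n consecutive
  // diagonal rows are ceil(m/n) columns apart and the connecting horizontal
  // run must stay inside the band
  int wmin = (m <= n) ? 1 : (int)std::ceil((double)m / (double)n);
  *widened = false;
  if (w < wmin) {
    w = wmin;
    *widened = true;
  }
  std::vector<double> cost((size_t)n * m, INF);
  std::vector<double> len((size_t)n * m, INF);
  double slope = (double)m / (double)n;

  for (int i = 1; i <= n; ++i) {
    double diag = i * slope;
    int j0 = (int)std::floor(diag - w);
    int j1 = (int)std::ceil(diag + w);
    if (j0 < 1) j0 = 1;
    if (j1 > m) j1 = m;
    for (int j = j0; j <= j1; ++j) {
      if (std::fabs(diag - (double)j) > (double)w) continue;
      double lc = local_cost(a + (size_t)(i - 1) * d, b + (size_t)(j - 1) * d,
                             d, geodesic);
      size_t id = (size_t)(i - 1) * m + (j - 1);
      if (i == 1 && j == 1) {
        cost[id] = lc;
        len[id] = 1.0;
        continue;
      }
      double best = INF, bestlen = INF;
      if (i > 1) {
        size_t up = (size_t)(i - 2) * m + (j - 1);
        if (cost[up] < best ||
            (cost[up] == best && len[up] + 1.0 < bestlen)) {
          best = cost[up];
          bestlen = len[up] + 1.0;
        }
      }
      if (j > 1) {
        size_t lt = (size_t)(i - 1) * m + (j - 2);
        if (cost[lt] < best ||
            (cost[lt] == best && len[lt] + 1.0 < bestlen)) {
          best = cost[lt];
          bestlen = len[lt] + 1.0;
        }
      }
      if (i > 1 && j > 1) {
        size_t dg = (size_t)(i - 2) * m + (j - 2);
        if (cost[dg] < best ||
            (cost[dg] == best && len[dg] + 1.0 < bestlen)) {
          best = cost[dg];
          bestlen = len[dg] + 1.0;
        }
      }
      if (best < INF) {
        cost[id] = best + lc;
        len[id] = bestlen;
      }
    }
  }
  size_t corner = (size_t)(n - 1) * m + (m - 1);
  *out_cost = cost[corner];
  *out_len = len[corner];
}

static void to_rowmajor(const NumericMatrix& x, std::vector<double>& out) {
  int n = x.nrow(), d = x.ncol();
  out.resize((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k)
      out[(size_t)i * d + k] = x(i, k);
}

// [[Rcpp::export]]
List dtw_band_cpp(NumericMatrix a, NumericMatrix b, double window_fraction,
                  bool geodesic = false) {
  int n = a.nrow(), m = b.nrow(), d = a.ncol();
  if (d != b.ncol()) stop("trajectories must share a dimension");
  if (n < 1 || m < 1) stop("trajectories must be nonempty");
  std::vector<double> av, bv;
  to_rowmajor(a, av);
  to_rowmajor(b, bv);
  double cost, len;
  bool widened;
  dtw_core(av.data(), bv.data(), n, m, d, window_fraction, geodesic,
           &cost, &len, &widened);
  if (!R_finite(cost)) stop("warping band disconnected the corners");
  return List::create(_["cumulative_distance"] = cost,
                      _["path_length"] = (double)len,
                      _["band_widened"] = widened);
}

// Per-joint DTW for two flattened quaternion sequences (frames x 4J).
// [[Rcpp::export]]
List motion_dtw_cpp(NumericMatrix a, NumericMatrix b, int n_joints,
                    double window_fraction, bool geodesic = false) {
  int n = a.nrow(), m = b.nrow();
  int d = a.ncol() / n_joints;
  if (a.ncol() != b.ncol() || a.ncol() % n_joints != 0)
    stop("flattened sequences do not match the joint count");
  NumericVector dist(n_joints), plen(n_joints);
  LogicalVector widened(n_joints);
  std::vector<double> av((size_t)n * d), bv((size_t)m * d);
  for (int jnt = 0; jnt < n_joints; ++jnt) {
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < d; ++k)
        av[(size_t)i * d + k] = a(i, jnt * d + k);
    for (int i = 0; i < m; ++i)
      for (int k = 0; k < d; ++k)
        bv[(size_t)i * d + k] = b(i, jnt * d + k);
    double cost, len;
    bool wdn;
    dtw_core(av.data(), bv.data(), n, m, d, window_fraction, geodesic,
             &cost, &len, &wdn);
    if (!R_finite(cost)) stop("warping band disconnected the corners");
    dist[jnt] = cost;
    plen[jnt] = len;
    widened[jnt] = wdn;
  }
  return List::create(_["cumulative_distance"] = dist,
                      _["path_length"] = plen,
                      _["band_widened"] = widened);
}
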