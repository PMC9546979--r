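// Nearest-neighbour information estimators.
//
// ksg_mi_cpp: Kraskov-Stoegbauer-Grassberger mutual information, algorithm 1
// (max-norm; counts use strict inequality against the k-th joint distance).
// fp_te_cpp: Frenzel-Pompe conditional mutual information
// I(x_past; y_future | y_past), i.e. transfer entropy x -> y, same counting
// convention. Both are O(n^2) and return nats.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static double kth_smallest(std::vector<double>& v, int k) {
  std::nth_element(v.begin(), v.begin() + (k - 1), v.end());
  return v[k - 1];
}

// [[Rcpp::export]]
double ksg_mi_cpp(NumericVector x, NumericVector y, int k) {
  const int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  if (k < 1 || k >= n) stop("k must be in [1, n)");
  std::vector<double> dz(n - 1);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = std::abs(x[j] - x[i]);
      double dy = std::abs(y[j] - y[i]);
      dz[m++] = dx > dy ? dx : dy;
    }
    double eps = kth_smallest(dz, k);
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (std::abs(x[j] - x[i]) < eps) ++nx;
      if (std::abs(y[j] - y[i]) < eps) ++ny;
    }
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
  }
  return R::digamma((double)k) + R::digamma((double)n) - acc / n;
}

static inline double rowdist(const NumericMatrix& m, int a, int b) {
  double d = 0.0;
  for (int c = 0; c < m.ncol(); ++c) {
    double v = std::abs(m(a, c) - m(b, c));
    if (v > d) d = v;
  }
  return d;
}

// [[Rcpp::export]]
double fp_te_cpp(NumericVector y_future, NumericMatrix y_past,
                 NumericMatrix x_past, int k) {
  const int n = y_future.size();
  if (y_past.nrow() != n || x_past.nrow() != n)
    stop("embedding row counts must match y_future length");
  if (k < 1 || k >= n) stop("k must be in [1, n)");
  std::vector<double> dz(n - 1);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double d = std::abs(y_future[j] - y_future[i]);
      double dyp = rowdist(y_past, i, j);
      if (dyp > d) d = dyp;
      double dxp = rowdist(x_past, i, j);
      if (dxp > d) d = dxp;
      dz[m++] = d;
    }
    double eps = kth_smallest(dz, k);
    int n_yp = 0, n_fyp = 0, n_xyp = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dyp = rowdist(y_past, i, j);
      if (dyp < eps) {
        ++n_yp;
        double df = std::abs(y_future[j] - y_future[i]);
        if ((df > dyp ? df : dyp) < eps) ++n_fyp;
        double dxp = rowdist(x_past, i, j);
        if ((dxp > dyp ? dxp : dyp) < eps) ++n_xyp;
      }
    }
    acc += R::digamma(n_yp + 1.0) - R::digamma(n_fyp + 1.0) -
           R::digamma(n_xyp + 1.0);
  }
  return R::digamma((double)k) + acc / n;
}
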