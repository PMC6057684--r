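#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Banded DTW with the symmetric step pattern. Local cost |a_i - b_j|;
// with symmetric2 = true the diagonal step carries weight 2 (the classical
// symmetric pattern), otherwise weight 1. Band: |i - j| <= band.
static double dtw_core(const double* a, int na, const double* b, int nb,
                       int band, bool symmetric2) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> prev(nb, INF), cur(nb, INF);
  double dw = symmetric2 ? 2.0 : 1.0;
  for (int i = 0; i < na; ++i) {
    int jlo = std::max(0, i - band), jhi = std::min(nb - 1, i + band);
    std::fill(cur.begin(), cur.end(), INF);
    for (int j = jlo; j <= jhi; ++j) {
      double c = std::fabs(a[i] - b[j]);
      if (i == 0 && j == 0) { cur[j] = c; continue; }
      double d1 = (i > 0 && j > 0) ? prev[j - 1] + dw * c : INF;
      double d2 = (i > 0) ? prev[j] + c : INF;
      double d3 = (j > 0) ? cur[j - 1] + c : INF;
      cur[j] = std::min(d1, std::min(d2, d3));
    }
    std::swap(prev, cur);
  }
  return prev[nb - 1];
}

static double ce_core(const double* x, int n) {
  double s = 0.0;
  for (int i = 0; i + 1 < n; ++i) {
    double d = x[i] - x[i + 1];
    s += d * d;
  }
  return std::sqrt(s);
}

// [[Rcpp::export(name = ".dtw_cpp")]]
double dtw_cpp(NumericVector a, NumericVector b, int band, bool symmetric2) {
  double v = dtw_core(a.begin(), a.size(), b.begin(), b.size(), band,
                      symmetric2);
  if (!R_FINITE(v))
    stop("Sakoe-Chiba band too narrow to admit any warping path");
  return v;
}

// [[Rcpp::export(name = ".ce_cpp")]]
double ce_cpp(NumericVector x) { return ce_core(x.begin(), x.size()); }

// Pairwise distance matrix over the rows of X. metric: 0 = euclidean,
// 1 = dtw, 2 = cid (euclidean x complexity factor), 3 = cid_dtw.
// [[Rcpp::export(name = ".pairwise_cpp")]]
NumericMatrix pairwise_cpp(NumericMatrix X, int metric, int band,
                           bool symmetric2, double eps) {
  int n = X.nrow(), m = X.ncol();
  NumericMatrix D(n, n);
  std::vector<std::vector<double> > rows(n, std::vector<double>(m));
  std::vector<double> ce(n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) rows[i][j] = X(i, j);
    if (metric == 2 || metric == 3) ce[i] = ce_core(&rows[i][0], m);
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d;
      if (metric == 0 || metric == 2) {
        double s = 0.0;
        for (int t = 0; t < m; ++t) {
          double df = rows[i][t] - rows[j][t];
          s += df * df;
        }
        d = std::sqrt(s);
      } else {
        d = dtw_core(&rows[i][0], m, &rows[j][0], m, band, symmetric2);
      }
      if (metric == 2 || metric == 3) {
        double hi = std::max(ce[i], ce[j]), lo = std::min(ce[i], ce[j]);
        double cf = (hi <= eps) ? 1.0 : hi / std::max(lo, eps);
        d *= cf;
      }
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}

// Cross distances between rows of X (new) and rows of Y (reference).
// [[Rcpp::export(name = ".cross_cpp")]]
NumericMatrix cross_cpp(NumericMatrix X, NumericMatrix Y, int metric,
                        int band, bool symmetric2, double eps) {
  int nx = X.nrow(), ny = Y.nrow(), m = X.ncol();
  if (Y.ncol() != m) stop("row length mismatch");
  NumericMatrix D(nx, ny);
  std::vector<double> cex(nx), cey(ny);
  std::vector<std::vector<double> > rx(nx, std::vector<double>(m)),
      ry(ny, std::vector<double>(m));
  for (int i = 0; i < nx; ++i) {
    for (int t = 0; t < m; ++t) rx[i][t] = X(i, t);
    cex[i] = ce_core(&rx[i][0], m);
  }
  for (int j = 0; j < ny; ++j) {
    for (int t = 0; t < m; ++t) ry[j][t] = Y(j, t);
    cey[j] = ce_core(&ry[j][0], m);
  }
  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) {
      double d;
      if (metric == 0 || metric == 2) {
        double s = 0.0;
        for (int t = 0; t < m; ++t) {
          double df = rx[i][t] - ry[j][t];
          s += df * df;
        }
        d = std::sqrt(s);
      } else {
        d = dtw_core(&rx[i][0], m, &ry[j][0], m, band, symmetric2);
      }
      if (metric == 2 || metric == 3) {
        double hi = std::max(cex[i], cey[j]), lo = std::min(cex[i], cey[j]);
        double cf = (hi <= eps) ? 1.0 : hi / std::max(lo, eps);
        d *= cf;
      }
      D(i, j) = d;
    }
  }
  return D;
}
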