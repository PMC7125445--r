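#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Band half-width in cells for a Sakoe-Chiba constraint of fraction r on
// length-n series. ceil(r*n), at least 1 cell so the diagonal is reachable.
static inline int band_width(int n, double r) {
  int w = (int)std::ceil(r * n);
  if (w < 1) w = 1;
  return w;
}

// Constrained DTW between equal-length series: squared point cost summed
// along the optimal monotone path restricted to |i-j| <= w, square-rooted.
static double dtw_core(const double* a, const double* b, int n, int w) {
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> prev(n + 1, inf), cur(n + 1, inf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(1, i - w), jhi = std::min(n, i + w);
    std::fill(cur.begin(), cur.end(), inf);
    for (int j = jlo; j <= jhi; ++j) {
      double d = a[i - 1] - b[j - 1];
      double best = prev[j - 1];             // diagonal
      if (prev[j] < best) best = prev[j];    // insertion
      if (cur[j - 1] < best) best = cur[j - 1]; // deletion
      cur[j] = d * d + best;
    }
    std::swap(prev, cur);
  }
  return std::sqrt(prev[n]);
}

// [[Rcpp::export(name = ".dtw_band_cpp")]]
double dtw_band_cpp(NumericVector a, NumericVector b, double r) {
  int n = a.size();
  if (b.size() != n) stop("series must have equal length");
  return dtw_core(REAL(a), REAL(b), n, band_width(n, r));
}

// Pairwise constrained DTW distances between the rows of A (queries) and
// the rows of B (references); used by 1-NN-DTW prediction.
// [[Rcpp::export(name = ".dtw_cross_cpp")]]
NumericMatrix dtw_cross_cpp(NumericMatrix A, NumericMatrix B, double r) {
  int n = A.ncol();
  if (B.ncol() != n) stop("series must have equal length");
  int w = band_width(n, r);
  NumericMatrix D(A.nrow(), B.nrow());
  std::vector<double> av(n), bv(n);
  for (int i = 0; i < A.nrow(); ++i) {
    for (int k = 0; k < n; ++k) av[k] = A(i, k);
    for (int j = 0; j < B.nrow(); ++j) {
      for (int k = 0; k < n; ++k) bv[k] = B(j, k);
      D(i, j) = dtw_core(av.data(), bv.data(), n, w);
    }
  }
  return D;
}

// Optimal warping path (1-based index pairs) of series s against template t
// under the band constraint; ties prefer the diagonal step. Used by DBA.
// [[Rcpp::export(name = ".dtw_path_cpp")]]
IntegerMatrix dtw_path_cpp(NumericVector s, NumericVector t, double r) {
  int n = s.size();
  if (t.size() != n) stop("series must have equal length");
  int w = band_width(n, r);
  const double inf = std::numeric_limits<double>::infinity();
  NumericMatrix D(n + 1, n + 1);
  std::fill(D.begin(), D.end(), inf);
  D(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(1, i - w), jhi = std::min(n, i + w);
    for (int j = jlo; j <= jhi; ++j) {
      double d = s[i - 1] - t[j - 1];
      double best = D(i - 1, j - 1);
      if (D(i - 1, j) < best) best = D(i - 1, j);
      if (D(i, j - 1) < best) best = D(i, j - 1);
      D(i, j) = d * d + best;
    }
  }
  // backtrack
  std::vector<int> pi, pj;
  int i = n, j = n;
  while (i > 0 || j > 0) {
    pi.push_back(i); pj.push_back(j);
    if (i == 0) { --j; continue; }
    if (j == 0) { --i; continue; }
    double dd = D(i - 1, j - 1), du = D(i - 1, j), dl = D(i, j - 1);
    if (dd <= du && dd <= dl) { --i; --j; }
    else if (du <= dl) { --i; }
    else { --j; }
  }
  int m = pi.size();
  IntegerMatrix P(m, 2);
  for (int k = 0; k < m; ++k) { // reverse into chronological order
    P(k, 0) = pi[m - 1 - k];
    P(k, 1) = pj[m - 1 - k];
  }
  return P;
}
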