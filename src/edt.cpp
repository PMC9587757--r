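#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Exact Euclidean distance transform (separable lower-envelope-of-parabolas,
// Felzenszwalb & Huttenlocher 2012), one 1D pass per axis. The input holds
// squared distances: 0 at background seeds, +Inf elsewhere. Anisotropic
// sampling is handled by the per-axis step. Sources at +Inf never contribute
// to the lower envelope and are skipped.

static void dt1d(const double* f, double* d, int n, double step) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double s2 = step * step;
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (!R_finite(f[q])) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s;
    while (true) {
      const int p = v[k];
      s = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (s <= z[k]) {
        --k;
        if (k < 0) break;
      } else break;
    }
    ++k;
    v[k] = q;
    z[k] = (k == 0) ? -INF : s;
    z[k + 1] = INF;
  }
  if (k < 0) { // no finite source in this line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < q) ++j;
    d[q] = f[v[j]] + s2 * (q - v[j]) * (q - v[j]);
  }
}

// dims: length 2 (ny, nx) or 3 (ny, nx, nz); column-major R layout.
// spacing: physical step per axis, same order as dims.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(NumericVector f0, IntegerVector dims, NumericVector spacing) {
  const int nd = dims.size();
  R_xlen_t ntot = 1;
  for (int i = 0; i < nd; ++i) ntot *= dims[i];
  NumericVector out(clone(f0));
  double* a = REAL(out);

  std::vector<R_xlen_t> stride(nd, 1);
  for (int i = 1; i < nd; ++i) stride[i] = stride[i - 1] * dims[i - 1];

  std::vector<double> line, dline;
  for (int ax = 0; ax < nd; ++ax) {
    const int n = dims[ax];
    const R_xlen_t st = stride[ax];
    line.resize(n);
    dline.resize(n);
    const R_xlen_t nlines = ntot / n;
    for (R_xlen_t l = 0; l < nlines; ++l) {
      R_xlen_t rem = l, base = 0;
      for (int i = 0; i < nd; ++i) {
        if (i == ax) continue;
        R_xlen_t idx = rem % dims[i];
        rem /= dims[i];
        base += idx * stride[i];
      }
      for (int q = 0; q < n; ++q) line[q] = a[base + q * st];
      dt1d(line.data(), dline.data(), n, spacing[ax]);
      for (int q = 0; q < n; ++q) a[base + q * st] = dline[q];
    }
  }
  return out;
}
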