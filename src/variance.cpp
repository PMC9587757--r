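#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Local directional variance maps over cubic/square neighbourhoods.
// 2D: circular variance of doubled angles, V = 1 - |mean resultant|.
// 3D: orientation-tensor variance, V = 3/2 * (1 - lambda1(mean(u u^T))),
// both in [0, 1]: 0 = perfectly parallel, 1 = isotropic.

static double lam1_3x3(double a[3][3]) {
  // largest eigenvalue by Jacobi sweeps (matrix destroyed)
  for (int sweep = 0; sweep < 32; ++sweep) {
    double off = std::fabs(a[0][1]) + std::fabs(a[0][2]) + std::fabs(a[1][2]);
    if (off < 1e-14) break;
    for (int p = 0; p < 2; ++p) {
      for (int q = p + 1; q < 3; ++q) {
        if (std::fabs(a[p][q]) < 1e-30) continue;
        const double phi = 0.5 * std::atan2(2.0 * a[p][q], a[q][q] - a[p][p]);
        const double c = std::cos(phi), s = std::sin(phi);
        for (int k = 0; k < 3; ++k) {
          const double akp = a[k][p], akq = a[k][q];
          a[k][p] = c * akp - s * akq;
          a[k][q] = s * akp + c * akq;
        }
        for (int k = 0; k < 3; ++k) {
          const double apk = a[p][k], aqk = a[q][k];
          a[p][k] = c * apk - s * aqk;
          a[q][k] = s * apk + c * aqk;
        }
      }
    }
  }
  double l = a[0][0];
  if (a[1][1] > l) l = a[1][1];
  if (a[2][2] > l) l = a[2][2];
  return l;
}

// theta/phi in degrees, NaN = invalid; phi may be length 0 for 2D fields.
// [[Rcpp::export]]
NumericVector cpp_local_variance(NumericVector theta, NumericVector phi,
                                 IntegerVector dims, int nbhd, int min_count) {
  const int nd = dims.size();
  const int ny = dims[0], nx = dims[1], nz = (nd == 3) ? dims[2] : 1;
  const R_xlen_t sxy = (R_xlen_t)ny * nx;
  const R_xlen_t ntot = sxy * nz;
  const bool is3d = (phi.size() == ntot);
  const double* TH = REAL(theta);
  const double* PH = is3d ? REAL(phi) : nullptr;
  NumericVector out(ntot, NA_REAL);
  double* V = REAL(out);
  const int r = nbhd / 2;
  const double d2r = M_PI / 180.0;

  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        const R_xlen_t c = y + (R_xlen_t)x * ny + (R_xlen_t)z * sxy;
        if (!R_finite(TH[c])) continue;
        int n = 0;
        double cs = 0, sn = 0;
        double T00 = 0, T01 = 0, T02 = 0, T11 = 0, T12 = 0, T22 = 0;
        const int zlo = (nd == 3) ? std::max(0, z - r) : 0;
        const int zhi = (nd == 3) ? std::min(nz - 1, z + r) : 0;
        for (int zz = zlo; zz <= zhi; ++zz) {
          for (int xx = std::max(0, x - r); xx <= std::min(nx - 1, x + r); ++xx) {
            const R_xlen_t col = (R_xlen_t)xx * ny + (R_xlen_t)zz * sxy;
            for (int yy = std::max(0, y - r); yy <= std::min(ny - 1, y + r); ++yy) {
              const R_xlen_t q = col + yy;
              if (!R_finite(TH[q])) continue;
              if (is3d) {
                const double t = TH[q] * d2r, p = PH[q] * d2r;
                const double ux = std::sin(p) * std::cos(t);
                const double uy = std::sin(p) * std::sin(t);
                const double uz = std::cos(p);
                T00 += ux * ux; T01 += ux * uy; T02 += ux * uz;
                T11 += uy * uy; T12 += uy * uz; T22 += uz * uz;
              } else {
                cs += std::cos(2.0 * TH[q] * d2r);
                sn += std::sin(2.0 * TH[q] * d2r);
              }
              ++n;
            }
          }
        }
        if (n < min_count) continue;
        double v;
        if (is3d) {
          double A[3][3] = {{T00 / n, T01 / n, T02 / n},
                            {T01 / n, T11 / n, T12 / n},
                            {T02 / n, T12 / n, T22 / n}};
          v = 1.5 * (1.0 - lam1_3x3(A));
        } else {
          v = 1.0 - std::sqrt(cs * cs + sn * sn) / n;
        }
        if (v < 0) v = 0;
        if (v > 1) v = 1;
        V[c] = v;
      }
    }
  }
  return out;
}
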