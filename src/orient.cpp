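#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Weighted orientation vector summation.
//
// 2D: for a centre pixel c, every other foreground pixel p inside the
// analysis window contributes the doubled-angle unit vector of direction
// p - c, weighted by w(p) = I(p) / |p-c|^expo.  theta = atan2 of the summed
// vector halved, mapped to [0, 180).  The doubled-angle representation makes
// the estimate axial (p and its point reflection contribute identically).
//
// 3D: contributions accumulate the weighted dyadic (outer-product) tensor of
// the unit direction; the dominant eigenvector of the CENTRAL tensor
// (raw second moment minus the rank-one mean-direction term) gives the
// axis. Subtracting the mean removes the inward-visibility bias at fiber
// surface voxels, where all neighbours lie to one side of the centre and
// the raw tensor's leading axis turns radial.

static inline double wrap180(double x) {
  x -= 180.0 * std::floor(x / 180.0);
  if (x >= 180.0) x = 0.0;
  if (x < 0.0) x = 0.0;
  return x;
}

// [[Rcpp::export]]
List cpp_orient2d(LogicalVector mask, NumericVector inten, IntegerVector win,
                  IntegerVector dims, double expo, bool circular, int min_nb) {
  const int ny = dims[0], nx = dims[1];
  const int* M = LOGICAL(mask);
  const double* I = REAL(inten);
  const int* W = INTEGER(win);
  NumericVector theta((R_xlen_t)ny * nx, NA_REAL);
  IntegerVector nnb((R_xlen_t)ny * nx, 0);
  double* TH = REAL(theta);
  int* NB = INTEGER(nnb);

  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      const R_xlen_t c = y + (R_xlen_t)x * ny;
      if (!M[c]) continue;
      const int r = W[c] / 2;
      const double r2max = (double)r * r;
      double cs = 0.0, sn = 0.0;
      int n = 0;
      const int xlo = std::max(0, x - r), xhi = std::min(nx - 1, x + r);
      const int ylo = std::max(0, y - r), yhi = std::min(ny - 1, y + r);
      for (int xx = xlo; xx <= xhi; ++xx) {
        const R_xlen_t col = (R_xlen_t)xx * ny;
        const double dx = xx - x;
        for (int yy = ylo; yy <= yhi; ++yy) {
          if (!M[col + yy]) continue;
          if (yy == y && xx == x) continue;
          const double dy = yy - y;
          const double rr2 = dx * dx + dy * dy;
          if (circular && rr2 > r2max) continue;
          const double w = I[col + yy] * std::pow(rr2, -expo / 2.0);
          cs += w * (dx * dx - dy * dy) / rr2;
          sn += w * (2.0 * dx * dy) / rr2;
          ++n;
        }
      }
      NB[c] = n;
      if (n >= min_nb) {
        TH[c] = wrap180(0.5 * std::atan2(sn, cs) * 180.0 / M_PI);
      }
    }
  }
  return List::create(_["theta"] = theta, _["n_neighbors"] = nnb);
}

// Jacobi eigen-decomposition of a symmetric 3x3 matrix; returns eigenvalues
// in descending order and the corresponding eigenvectors as columns.
static void eig3(double a[3][3], double lam[3], double vec[3][3]) {
  double v[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
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
        for (int k = 0; k < 3; ++k) {
          const double vkp = v[k][p], vkq = v[k][q];
          v[k][p] = c * vkp - s * vkq;
          v[k][q] = s * vkp + c * vkq;
        }
      }
    }
  }
  int ord[3] = {0, 1, 2};
  double d[3] = {a[0][0], a[1][1], a[2][2]};
  for (int i = 0; i < 2; ++i)
    for (int j = i + 1; j < 3; ++j)
      if (d[ord[j]] > d[ord[i]]) std::swap(ord[i], ord[j]);
  for (int i = 0; i < 3; ++i) {
    lam[i] = d[ord[i]];
    for (int k = 0; k < 3; ++k) vec[k][i] = v[k][ord[i]];
  }
}

// Axis angles from a unit axis, canonicalized so that the pair
// (theta, phi), theta in [0,180), phi in [0,180), reconstructs the axis as
// u = (sin phi cos theta, sin phi sin theta, cos phi): flip the sign so the
// y-component is >= 0 (tie-break: x >= 0, then z >= 0).
static void axis_angles(double ux, double uy, double uz,
                        double* theta, double* phi) {
  const double eps = 1e-12;
  if (uy < -eps || (std::fabs(uy) <= eps && (ux < -eps ||
      (std::fabs(ux) <= eps && uz < 0)))) {
    ux = -ux; uy = -uy; uz = -uz;
  }
  double th;
  if (std::fabs(ux) <= eps && std::fabs(uy) <= eps) {
    th = 0.0; // polar axis: azimuth undefined
  } else {
    th = std::atan2(uy, ux) * 180.0 / M_PI;
    if (th < 0) th = 0.0;          // uy >= 0 guarantees [0, 180]
    if (th >= 180.0) th = 0.0;
  }
  double cz = uz;
  if (cz > 1.0) cz = 1.0;
  if (cz < -1.0) cz = -1.0;
  *theta = th;
  *phi = std::acos(cz) * 180.0 / M_PI;
  if (*phi >= 180.0) *phi -= 180.0;
}

// centers: 0-based flat indices of the voxels to evaluate (empty = all
// foreground). For each centre the cheaper of window scan / foreground-list
// scan is used, which keeps very large windows tractable.
// [[Rcpp::export]]
List cpp_orient3d(LogicalVector mask, NumericVector inten, IntegerVector win,
                  IntegerVector dims, double expo, bool circular, int min_nb,
                  double tie_tol, IntegerVector centers) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t sxy = (R_xlen_t)ny * nx;
  const R_xlen_t ntot = sxy * nz;
  const int* M = LOGICAL(mask);
  const double* I = REAL(inten);
  const int* W = INTEGER(win);

  std::vector<R_xlen_t> fg;
  fg.reserve(1024);
  for (R_xlen_t i = 0; i < ntot; ++i)
    if (M[i]) fg.push_back(i);

  std::vector<R_xlen_t> cts;
  if (centers.size() == 0) {
    cts = fg;
  } else {
    cts.reserve(centers.size());
    for (int i = 0; i < centers.size(); ++i) cts.push_back(centers[i]);
  }

  NumericVector theta(ntot, NA_REAL), phi(ntot, NA_REAL);
  IntegerVector nnb(ntot, 0);
  double* TH = REAL(theta);
  double* PH = REAL(phi);
  int* NB = INTEGER(nnb);

  for (R_xlen_t ci = 0; ci < (R_xlen_t)cts.size(); ++ci) {
    const R_xlen_t c = cts[ci];
    if (!M[c]) continue;
    const int y = (int)(c % ny);
    const int x = (int)((c / ny) % nx);
    const int z = (int)(c / sxy);
    const int r = W[c] / 2;
    const double r2max = (double)r * r;
    double T00 = 0, T01 = 0, T02 = 0, T11 = 0, T12 = 0, T22 = 0;
    double Sx = 0, Sy = 0, Sz = 0, Wsum = 0;
    int n = 0;
    const int ylo = std::max(0, y - r), yhi = std::min(ny - 1, y + r);
    const int xlo = std::max(0, x - r), xhi = std::min(nx - 1, x + r);
    const int zlo = std::max(0, z - r), zhi = std::min(nz - 1, z + r);
    const double cube = (double)(yhi - ylo + 1) * (xhi - xlo + 1) * (zhi - zlo + 1);

    auto accumulate = [&](int yy, int xx, int zz, R_xlen_t q) {
      const double dy = yy - y, dx = xx - x, dz = zz - z;
      const double rr2 = dy * dy + dx * dx + dz * dz;
      if (rr2 == 0.0) return;
      if (circular && rr2 > r2max) return;
      const double w = I[q] * std::pow(rr2, -expo / 2.0);
      const double inv = w / rr2; // w * (u u^T) with u = d / |d|
      T00 += inv * dx * dx; T01 += inv * dx * dy; T02 += inv * dx * dz;
      T11 += inv * dy * dy; T12 += inv * dy * dz; T22 += inv * dz * dz;
      const double rr = std::sqrt(rr2);
      Sx += w * dx / rr; Sy += w * dy / rr; Sz += w * dz / rr;
      Wsum += w;
      ++n;
    };

    if (cube <= (double)fg.size()) {
      for (int zz = zlo; zz <= zhi; ++zz) {
        for (int xx = xlo; xx <= xhi; ++xx) {
          const R_xlen_t col = (R_xlen_t)xx * ny + (R_xlen_t)zz * sxy;
          for (int yy = ylo; yy <= yhi; ++yy) {
            const R_xlen_t q = col + yy;
            if (M[q]) accumulate(yy, xx, zz, q);
          }
        }
      }
    } else {
      for (const R_xlen_t q : fg) {
        const int yy = (int)(q % ny);
        const int xx = (int)((q / ny) % nx);
        const int zz = (int)(q / sxy);
        if (yy < ylo || yy > yhi || xx < xlo || xx > xhi || zz < zlo || zz > zhi)
          continue;
        accumulate(yy, xx, zz, q);
      }
    }

    NB[c] = n;
    if (n < min_nb || Wsum <= 0) continue;
    const double mx = Sx / Wsum, my = Sy / Wsum, mz = Sz / Wsum;
    double A[3][3] = {
      {T00 / Wsum - mx * mx, T01 / Wsum - mx * my, T02 / Wsum - mx * mz},
      {T01 / Wsum - mx * my, T11 / Wsum - my * my, T12 / Wsum - my * mz},
      {T02 / Wsum - mx * mz, T12 / Wsum - my * mz, T22 / Wsum - mz * mz}};
    double lam[3], vec[3][3];
    eig3(A, lam, vec);
    if (lam[0] <= 1e-12) continue;
    if ((lam[0] - lam[1]) / lam[0] < tie_tol) continue; // orientation undefined
    double th, ph;
    axis_angles(vec[0][0], vec[1][0], vec[2][0], &th, &ph);
    TH[c] = th;
    PH[c] = ph;
  }
  return List::create(_["theta"] = theta, _["phi"] = phi,
                      _["n_neighbors"] = nnb);
}
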