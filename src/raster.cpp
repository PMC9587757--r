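#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Phantom fiber rasterizer. A fiber is a polyline axis (2 points for a
// straight fiber, densely sampled for a curvy one) dilated to `radius`:
// a pixel is foreground iff its centre lies within `radius` of the axis.
// Ground truth at a pixel is the tangent orientation at the nearest axis
// point. The distance field also provides a one-pixel partial-volume
// intensity ramp at the fiber edge.
//
// Overlap handling: with `forbid`, placement fails (nothing painted) if any
// pixel within radius + gap of the axis is already foreground. Otherwise
// contested pixels keep the truth of the axis they are closest to, in
// radius-relative units (`claim` stores the winning relative distance).

// [[Rcpp::export]]
bool cpp_place_polyline(LogicalVector mask, NumericVector inten,
                        NumericVector theta_true, NumericVector phi_true,
                        NumericVector thick_true, NumericVector claim,
                        IntegerVector dims, NumericMatrix pts,
                        NumericVector tang_theta, NumericVector tang_phi,
                        double radius, double gap, double fg, double bg,
                        bool forbid) {
  const int nd = dims.size();
  const int ny = dims[0], nx = dims[1], nz = (nd == 3) ? dims[2] : 1;
  const R_xlen_t sxy = (R_xlen_t)ny * nx;
  const int k = pts.nrow();
  int* M = LOGICAL(mask);
  double* I = REAL(inten);
  double* TT = REAL(theta_true);
  double* PT = (nd == 3) ? REAL(phi_true) : nullptr;
  double* KT = REAL(thick_true);
  double* CL = REAL(claim);

  const double reach = radius + std::max(gap, 1.0) + 1.0;
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf,
         zmin = 0, zmax = 0;
  if (nd == 3) { zmin = R_PosInf; zmax = R_NegInf; }
  for (int i = 0; i < k; ++i) {
    xmin = std::min(xmin, pts(i, 0)); xmax = std::max(xmax, pts(i, 0));
    ymin = std::min(ymin, pts(i, 1)); ymax = std::max(ymax, pts(i, 1));
    if (nd == 3) {
      zmin = std::min(zmin, pts(i, 2)); zmax = std::max(zmax, pts(i, 2));
    }
  }
  const int xlo = std::max(0, (int)std::floor(xmin - reach));
  const int xhi = std::min(nx - 1, (int)std::ceil(xmax + reach));
  const int ylo = std::max(0, (int)std::floor(ymin - reach));
  const int yhi = std::min(ny - 1, (int)std::ceil(ymax + reach));
  const int zlo = (nd == 3) ? std::max(0, (int)std::floor(zmin - reach)) : 0;
  const int zhi = (nd == 3) ? std::min(nz - 1, (int)std::ceil(zmax + reach)) : 0;

  // nearest axis point: squared distance + index (fractional along segment)
  auto nearest = [&](double px, double py, double pz, double* d2out) -> int {
    double best = R_PosInf;
    int besti = 0;
    for (int i = 0; i + 1 < k || (k == 1 && i == 0); ++i) {
      double ax = pts(i, 0), ay = pts(i, 1);
      double az = (nd == 3) ? pts(i, 2) : 0.0;
      double t = 0.0, cx = ax, cy = ay, cz = az;
      int idx = i;
      if (k > 1) {
        const double bx = pts(i + 1, 0), by = pts(i + 1, 1);
        const double bz = (nd == 3) ? pts(i + 1, 2) : 0.0;
        const double vx = bx - ax, vy = by - ay, vz = bz - az;
        const double L2 = vx * vx + vy * vy + vz * vz;
        t = (L2 > 0) ? ((px - ax) * vx + (py - ay) * vy + (pz - az) * vz) / L2
                     : 0.0;
        t = std::max(0.0, std::min(1.0, t));
        cx = ax + t * vx; cy = ay + t * vy; cz = az + t * vz;
        idx = (t > 0.5) ? i + 1 : i;
      }
      const double dx = px - cx, dy = py - cy, dz = pz - cz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; besti = idx; }
      if (k == 1) break;
    }
    *d2out = best;
    return besti;
  };

  // pass 1: collision / emptiness check
  bool any_inside = false;
  const double rr = radius, rg2 = (radius + gap) * (radius + gap);
  for (int z = zlo; z <= zhi; ++z) {
    for (int x = xlo; x <= xhi; ++x) {
      const R_xlen_t col = (R_xlen_t)x * ny + (R_xlen_t)z * sxy;
      for (int y = ylo; y <= yhi; ++y) {
        double d2;
        nearest(x, y, z, &d2);
        if (forbid && d2 <= rg2 && M[col + y]) return false;
        if (d2 <= rr * rr) any_inside = true;
      }
    }
  }
  if (!any_inside) return false;

  // pass 2: paint
  for (int z = zlo; z <= zhi; ++z) {
    for (int x = xlo; x <= xhi; ++x) {
      const R_xlen_t col = (R_xlen_t)x * ny + (R_xlen_t)z * sxy;
      for (int y = ylo; y <= yhi; ++y) {
        double d2;
        const int ni = nearest(x, y, z, &d2);
        const double d = std::sqrt(d2);
        if (d > radius + 1.0) continue;
        const R_xlen_t i = col + y;
        const double cov = std::min(1.0, std::max(0.0, radius + 0.5 - d));
        if (cov > 0) {
          const double val = bg + (fg - bg) * cov;
          if (val > I[i]) I[i] = val;
        }
        if (d <= radius) {
          M[i] = TRUE;
          const double rel = d / radius;
          if (rel < CL[i]) {
            CL[i] = rel;
            TT[i] = tang_theta[ni];
            if (PT) PT[i] = tang_phi[ni];
            KT[i] = 2.0 * radius;
          }
        }
      }
    }
  }
  return true;
}
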