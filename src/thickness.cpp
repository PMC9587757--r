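#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Distance transfer: every foreground pixel receives the diameter of the
// largest inscribed disc/sphere (measured on the refined grid) that covers
// it. Discs are seeded at distance-ridge points only: a point is dominated
// (and skipped) when a neighbour's disc fully contains its own, which leaves
// the medial-axis-like seed set and makes the painting pass cheap. Painting
// in descending disc order with an overwrite-if-greater rule reproduces the
// exact per-pixel maximum over all covering discs.

struct Seed { double val; R_xlen_t idx; };

// edt: Euclidean distance to nearest background pixel centre (refined grid,
// already square-rooted); 0/neg values are background. dims length 2 or 3.
// [[Rcpp::export]]
NumericVector cpp_distance_transfer(NumericVector edt, IntegerVector dims) {
  const int nd = dims.size();
  const int ny = dims[0], nx = dims[1], nz = (nd == 3) ? dims[2] : 1;
  const R_xlen_t sxy = (R_xlen_t)ny * nx;
  const R_xlen_t ntot = sxy * nz;
  const double* E = REAL(edt);
  NumericVector out(ntot);
  double* T = REAL(out);

  std::vector<Seed> seeds;
  seeds.reserve(1024);

  // ridge detection: keep (y,x,z) unless a neighbour q has E[q] >= E[p] + |q-p|
  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        const R_xlen_t p = y + (R_xlen_t)x * ny + (R_xlen_t)z * sxy;
        const double d = E[p];
        if (d <= 0) continue;
        bool dominated = false;
        for (int dz = (nd == 3 ? -1 : 0); dz <= (nd == 3 ? 1 : 0) && !dominated; ++dz) {
          const int zz = z + dz;
          if (zz < 0 || zz >= nz) continue;
          for (int dx = -1; dx <= 1 && !dominated; ++dx) {
            const int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            for (int dy = -1; dy <= 1; ++dy) {
              if (dy == 0 && dx == 0 && dz == 0) continue;
              const int yy = y + dy;
              if (yy < 0 || yy >= ny) continue;
              const R_xlen_t q = yy + (R_xlen_t)xx * ny + (R_xlen_t)zz * sxy;
              const double step = std::sqrt((double)(dy * dy + dx * dx + dz * dz));
              if (E[q] >= d + step - 1e-9) { dominated = true; break; }
            }
          }
        }
        if (!dominated) seeds.push_back({d, p});
      }
    }
  }

  std::sort(seeds.begin(), seeds.end(),
            [](const Seed& a, const Seed& b) { return a.val > b.val; });

  for (const Seed& s : seeds) {
    const double d = s.val;
    const double v = 2.0 * d;       // diameter carried by this disc
    const double d2 = d * d + 1e-9;
    const int r = (int)std::ceil(d);
    const int y = (int)(s.idx % ny);
    const int x = (int)((s.idx / ny) % nx);
    const int z = (int)(s.idx / sxy);
    const int z0 = (nd == 3) ? std::max(0, z - r) : 0;
    const int z1 = (nd == 3) ? std::min(nz - 1, z + r) : 0;
    for (int zz = z0; zz <= z1; ++zz) {
      const double dz2 = (double)(zz - z) * (zz - z);
      for (int xx = std::max(0, x - r); xx <= std::min(nx - 1, x + r); ++xx) {
        const double dxz2 = dz2 + (double)(xx - x) * (xx - x);
        if (dxz2 > d2) continue;
        const int span = (int)std::floor(std::sqrt(d2 - dxz2));
        const R_xlen_t col = (R_xlen_t)xx * ny + (R_xlen_t)zz * sxy;
        const int ylo = std::max(0, y - span), yhi = std::min(ny - 1, y + span);
        for (int yy = ylo; yy <= yhi; ++yy) {
          double* t = T + col + yy;
          if (*t < v) *t = v;
        }
      }
    }
  }
  return out;
}

// Nearest-neighbour refinement of a logical mask by an integer factor.
// [[Rcpp::export]]
LogicalVector cpp_upsample_mask(LogicalVector mask, IntegerVector dims, int f) {
  const int nd = dims.size();
  const int ny = dims[0], nx = dims[1], nz = (nd == 3) ? dims[2] : 1;
  const int NY = ny * f, NX = nx * f, NZ = (nd == 3) ? nz * f : 1;
  const R_xlen_t SXY = (R_xlen_t)NY * NX;
  LogicalVector out((R_xlen_t)NY * NX * NZ);
  const int* m = LOGICAL(mask);
  int* o = LOGICAL(out);
  for (int Z = 0; Z < NZ; ++Z) {
    const R_xlen_t zoff = (R_xlen_t)(Z / f) * ny * nx;
    for (int X = 0; X < NX; ++X) {
      const R_xlen_t coff = zoff + (R_xlen_t)(X / f) * ny;
      const R_xlen_t Coff = (R_xlen_t)Z * SXY + (R_xlen_t)X * NY;
      for (int Y = 0; Y < NY; ++Y) o[Coff + Y] = m[coff + Y / f];
    }
  }
  return out;
}

// Block-max downsampling by factor f (used to return refined thickness to
// the original grid).
// [[Rcpp::export]]
NumericVector cpp_downsample_max(NumericVector v, IntegerVector fine_dims, int f) {
  const int nd = fine_dims.size();
  const int NY = fine_dims[0], NX = fine_dims[1], NZ = (nd == 3) ? fine_dims[2] : 1;
  const int ny = NY / f, nx = NX / f, nz = (nd == 3) ? NZ / f : 1;
  const R_xlen_t SXY = (R_xlen_t)NY * NX;
  NumericVector out((R_xlen_t)ny * nx * nz);
  const double* a = REAL(v);
  double* o = REAL(out);
  for (int Z = 0; Z < NZ; ++Z) {
    const R_xlen_t ozoff = (R_xlen_t)(Z / f) * ny * nx;
    for (int X = 0; X < NX; ++X) {
      const R_xlen_t ooff = ozoff + (R_xlen_t)(X / f) * ny;
      const R_xlen_t coff = (R_xlen_t)Z * SXY + (R_xlen_t)X * NY;
      for (int Y = 0; Y < NY; ++Y) {
        const R_xlen_t oi = ooff + Y / f;
        const double val = a[coff + Y];
        if (val > o[oi]) o[oi] = val;
      }
    }
  }
  return out;
}
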