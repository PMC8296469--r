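#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// One search-lattice offset: position shift in fractional voxel units per
// axis plus its precomputed squared-distance term (d/dta)^2.
struct Offset {
  double fx, fy, fz;
  double dist2_term;
};

static inline double trilinear(const double *v, int nx, int ny, int nz,
                               double fx, double fy, double fz) {
  int x0 = (int)std::floor(fx); if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
  int y0 = (int)std::floor(fy); if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
  int z0 = (int)std::floor(fz); if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
  double wx = fx - x0, wy = fy - y0, wz = fz - z0;
  // singleton axes: zero stride so the (weight-0) partner sample stays in bounds
  long long sx = nx > 1 ? 1 : 0, sy = ny > 1 ? nx : 0,
            sz = nz > 1 ? (long long)nx * ny : 0;
  const double *p = v + x0 * sx + y0 * sy + z0 * sz;
  double c00 = p[0] + wx * (p[sx] - p[0]);
  double c10 = p[sy] + wx * (p[sy + sx] - p[sy]);
  double c01 = p[sz] + wx * (p[sz + sx] - p[sz]);
  double c11 = p[sz + sy] + wx * (p[sz + sy + sx] - p[sz + sy]);
  double c0 = c00 + wy * (c10 - c00);
  double c1 = c01 + wy * (c11 - c01);
  return c0 + wz * (c1 - c0);
}

// Global gamma over the scored voxels. The search lattice is the isotropic
// grid of step `step` mm (axis-aligned integer multiples) truncated to the
// ball of radius `cap` mm, with the evaluated dose trilinearly interpolated
// at each lattice point. `brute = false` iterates offsets in increasing
// distance and stops once the distance term alone can no longer improve the
// minimum -- an exact pruning, so both modes return identical values.
// [[Rcpp::export]]
NumericVector gamma_engine_cpp(NumericVector ref, NumericVector eval,
                               IntegerVector dims, NumericVector spacing,
                               IntegerVector scored_idx0,
                               double dd_abs, double dta, double cap,
                               double step, bool brute) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double *rv = REAL(ref);
  const double *ev = REAL(eval);

  const int R = (int)std::floor(cap / step + 1e-12);
  std::vector<Offset> offs;
  offs.reserve((size_t)(4.5 * R * R * R) + 64);
  const double cap2 = cap * cap * (1.0 + 1e-12);
  for (int i = -R; i <= R; ++i)
    for (int j = -R; j <= R; ++j)
      for (int k = -R; k <= R; ++k) {
        double d2 = step * step * (double)(i * i + j * j + k * k);
        if (d2 <= cap2) {
          Offset o;
          o.fx = i * step / sx;
          o.fy = j * step / sy;
          o.fz = k * step / sz;
          o.dist2_term = d2 / (dta * dta);
          offs.push_back(o);
        }
      }
  std::sort(offs.begin(), offs.end(),
            [](const Offset &a, const Offset &b) { return a.dist2_term < b.dist2_term; });
  const size_t noff = offs.size();

  const R_xlen_t ns = scored_idx0.size();
  NumericVector out(ns);
  const double xmax = nx - 1.0, ymax = ny - 1.0, zmax = nz - 1.0;

  for (R_xlen_t s = 0; s < ns; ++s) {
    const long long idx = scored_idx0[s];
    const int ix = (int)(idx % nx);
    const int iy = (int)((idx / nx) % ny);
    const int iz = (int)(idx / ((long long)nx * ny));
    const double refval = rv[idx];
    double best = R_PosInf;
    for (size_t o = 0; o < noff; ++o) {
      const double t = offs[o].dist2_term;
      if (!brute && t >= best) break;  // sorted: nothing further can improve
      const double fx = ix + offs[o].fx;
      if (fx < 0.0 || fx > xmax) continue;
      const double fy = iy + offs[o].fy;
      if (fy < 0.0 || fy > ymax) continue;
      const double fz = iz + offs[o].fz;
      if (fz < 0.0 || fz > zmax) continue;
      const double diff = (trilinear(ev, nx, ny, nz, fx, fy, fz) - refval) / dd_abs;
      const double g2 = t + diff * diff;
      if (g2 < best) best = g2;
    }
    out[s] = std::sqrt(best);
  }
  return out;
}
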