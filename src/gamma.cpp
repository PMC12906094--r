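#include <Rcpp.h>
#include <array>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline double interp_one(const NumericVector &vol, const int *dimv,
                                const double *spacing, const double *origin,
                                double x, double y, double z, bool &ok) {
  const int nx = dimv[0], ny = dimv[1], nz = dimv[2];
  double fx = (x - origin[0]) / spacing[0];
  double fy = (y - origin[1]) / spacing[1];
  double fz = (z - origin[2]) / spacing[2];
  if (fx < 0 || fy < 0 || fz < 0 || fx > nx - 1 || fy > ny - 1 || fz > nz - 1) {
    ok = false;
    return 0.0;
  }
  ok = true;
  int ix = (int)std::floor(fx); if (ix > nx - 2) ix = nx > 1 ? nx - 2 : 0;
  int iy = (int)std::floor(fy); if (iy > ny - 2) iy = ny > 1 ? ny - 2 : 0;
  int iz = (int)std::floor(fz); if (iz > nz - 2) iz = nz > 1 ? nz - 2 : 0;
  double tx = fx - ix, ty = fy - iy, tz = fz - iz;
  if (nx == 1) { ix = 0; tx = 0; }
  if (ny == 1) { iy = 0; ty = 0; }
  if (nz == 1) { iz = 0; tz = 0; }
  const int sy = nx, sz = nx * ny;
  const int i000 = ix + iy * sy + iz * sz;
  const int dx = (nx > 1) ? 1 : 0, dy = (ny > 1) ? sy : 0, dz = (nz > 1) ? sz : 0;
  double c00 = vol[i000] * (1 - tx) + vol[i000 + dx] * tx;
  double c10 = vol[i000 + dy] * (1 - tx) + vol[i000 + dx + dy] * tx;
  double c01 = vol[i000 + dz] * (1 - tx) + vol[i000 + dx + dz] * tx;
  double c11 = vol[i000 + dy + dz] * (1 - tx) + vol[i000 + dx + dy + dz] * tx;
  double c0 = c00 * (1 - ty) + c10 * ty;
  double c1 = c01 * (1 - ty) + c11 * ty;
  return c0 * (1 - tz) + c1 * tz;
}

// Gamma index of `ev` against reference `ref` on a shared grid.
// dd_abs: absolute dose-difference criterion (Gy, global normalization done
// by the caller); dta: distance-to-agreement (mm); cutoff_abs: reference dose
// below which a point is not evaluated (NA in output); step: search lattice
// step (mm). Search is exhaustive over a ball of radius 3*dta on that
// lattice, with candidates visited in order of increasing distance so the
// scan can stop once the spatial term alone exceeds the current minimum.
// [[Rcpp::export]]
NumericVector cpp_gamma(NumericVector ref, NumericVector ev, IntegerVector dim,
                        NumericVector spacing, NumericVector origin,
                        double dd_abs, double dta, double cutoff_abs,
                        double step) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  int dimv[3] = {nx, ny, nz};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double org[3] = {origin[0], origin[1], origin[2]};
  const double radius = 3.0 * dta;
  // build candidate offsets (collapsed axes get only 0)
  const int kmax = (int)std::floor(radius / step);
  std::vector<double> axoff;
  for (int k = -kmax; k <= kmax; ++k) axoff.push_back(k * step);
  std::vector<std::array<double, 4>> offs;  // dx, dy, dz, r2
  const double r2max = radius * radius + 1e-12;
  for (double ox : (nx > 1 ? axoff : std::vector<double>{0.0}))
    for (double oy : (ny > 1 ? axoff : std::vector<double>{0.0}))
      for (double oz : (nz > 1 ? axoff : std::vector<double>{0.0})) {
        double r2 = ox * ox + oy * oy + oz * oz;
        if (r2 <= r2max) offs.push_back({ox, oy, oz, r2});
      }
  std::sort(offs.begin(), offs.end(),
            [](const std::array<double, 4> &a, const std::array<double, 4> &b) {
              return a[3] < b[3];
            });
  const double dta2 = dta * dta, dd2 = dd_abs * dd_abs;
  NumericVector out(ref.size());
  int idx = 0;
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix, ++idx) {
        double dr = ref[idx];
        if (dr < cutoff_abs) { out[idx] = NA_REAL; continue; }
        double x = org[0] + ix * sp[0];
        double y = org[1] + iy * sp[1];
        double z = org[2] + iz * sp[2];
        double best = std::numeric_limits<double>::infinity();
        for (size_t o = 0; o < offs.size(); ++o) {
          double r2 = offs[o][3] / dta2;
          if (r2 >= best) break;  // offsets sorted: no better candidate left
          bool ok;
          double de = interp_one(ev, dimv, sp, org, x + offs[o][0],
                                 y + offs[o][1], z + offs[o][2], ok);
          if (!ok) continue;
          double dd = de - dr;
          double g2 = r2 + dd * dd / dd2;
          if (g2 < best) best = g2;
        }
        out[idx] = std::sqrt(best);
      }
  return out;
}
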