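#include <Rcpp.h>
using namespace Rcpp;

// Water-equivalent radiological path (cm) from a source point to each target
// point, by exact Siddon-style voxel traversal of a density grid (g/cm^3,
// voxel-constant). Positions in mm; voxel i centered at origin + (i-1)*spacing,
// its cell extending half a spacing to either side.
// [[Rcpp::export]]
NumericVector cpp_raydepth(NumericVector dens, IntegerVector dim,
                           NumericVector spacing, NumericVector origin,
                           NumericVector src, NumericMatrix targets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n[3] = {nx, ny, nz};
  const int stride[3] = {1, nx, nx * ny};
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = origin[a] - 0.5 * spacing[a];
    hi[a] = origin[a] + (n[a] - 0.5) * spacing[a];
  }
  const int npts = targets.nrow();
  NumericVector out(npts);
  for (int p = 0; p < npts; ++p) {
    double d[3], s[3];
    for (int a = 0; a < 3; ++a) {
      s[a] = src[a];
      d[a] = targets(p, a) - src[a];
    }
    double raylen = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (raylen <= 0) { out[p] = 0.0; continue; }
    // clip parameter range to the grid box and to [0, 1] (stop at target)
    double tmin = 0.0, tmax = 1.0;
    bool miss = false;
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(d[a]) < 1e-12) {
        if (s[a] < lo[a] || s[a] > hi[a]) { miss = true; break; }
      } else {
        double t1 = (lo[a] - s[a]) / d[a];
        double t2 = (hi[a] - s[a]) / d[a];
        if (t1 > t2) std::swap(t1, t2);
        if (t1 > tmin) tmin = t1;
        if (t2 < tmax) tmax = t2;
      }
    }
    if (miss || tmax <= tmin) { out[p] = 0.0; continue; }
    // walk plane crossings
    double tnext[3], dt[3];
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(d[a]) < 1e-12) {
        tnext[a] = std::numeric_limits<double>::infinity();
        dt[a] = std::numeric_limits<double>::infinity();
      } else {
        dt[a] = spacing[a] / std::fabs(d[a]);
        double x0 = s[a] + tmin * d[a];
        double k = (x0 - lo[a]) / spacing[a];  // plane index coordinate
        double knext = (d[a] > 0) ? std::floor(k) + 1.0 : std::ceil(k) - 1.0;
        tnext[a] = (lo[a] + knext * spacing[a] - s[a]) / d[a];
        if (tnext[a] <= tmin + 1e-15) tnext[a] += dt[a];
      }
    }
    double acc = 0.0, tcur = tmin;
    while (tcur < tmax - 1e-15) {
      double tn = std::min(std::min(tnext[0], tnext[1]), std::min(tnext[2], tmax));
      double tm = 0.5 * (tcur + tn);
      int idx = 0;
      bool ok = true;
      for (int a = 0; a < 3; ++a) {
        double x = s[a] + tm * d[a];
        int i = (int)std::floor((x - lo[a]) / spacing[a]);
        if (i < 0) i = 0;
        if (i > n[a] - 1) i = n[a] - 1;
        if (!std::isfinite(x)) { ok = false; break; }
        idx += i * stride[a];
      }
      if (ok) acc += dens[idx] * (tn - tcur) * raylen;
      for (int a = 0; a < 3; ++a)
        if (tnext[a] <= tn + 1e-15) tnext[a] += dt[a];
      tcur = tn;
    }
    out[p] = acc / 10.0;  // mm * g/cm^3 -> g/cm^2 (cm water-equivalent)
  }
  return out;
}

static inline double edge_cdf(double x, double sigma) {
  // Gaussian CDF evaluated at distance x from an edge
  return 0.5 * (1.0 + std::erf(x / (sigma * M_SQRT2)));
}

// Fluence of a jaw + MLC aperture at beam's-eye-view points (u, v) in mm at
// the isocenter plane. The opening is a union of per-leaf rectangles
// (disjoint in v), each clipped by the jaws; the Gaussian penumbra
// convolution of such a union factorizes exactly into products of edge CDFs.
// mlc: 2 x N matrix (row 1 = bank A/left edge, row 2 = bank B/right edge),
// leafv: N+1 leaf boundary positions along v, jaw: (x1, x2, y1, y2), all mm.
// [[Rcpp::export]]
NumericVector cpp_fluence(NumericVector u, NumericVector v, NumericMatrix mlc,
                          NumericVector leafv, NumericVector jaw, double sigma) {
  const int npts = u.size(), nleaf = mlc.ncol();
  // leaves whose v-interval lies many sigmas from the point contribute
  // below 1e-9 and are skipped
  const double vcut = 6.5 * sigma;
  NumericVector out(npts);
  for (int p = 0; p < npts; ++p) {
    double up = u[p], vp = v[p], acc = 0.0;
    for (int l = 0; l < nleaf; ++l) {
      double a = std::max(mlc(0, l), jaw[0]);
      double b = std::min(mlc(1, l), jaw[1]);
      double vlo = std::max(leafv[l], jaw[2]);
      double vhi = std::min(leafv[l + 1], jaw[3]);
      if (b <= a || vhi <= vlo) continue;
      if (sigma > 0 && (vhi < vp - vcut || vlo > vp + vcut)) continue;
      if (sigma <= 0) {
        if (up >= a && up <= b && vp >= vlo && vp < vhi) acc += 1.0;
      } else {
        acc += (edge_cdf(b - up, sigma) - edge_cdf(a - up, sigma)) *
               (edge_cdf(vhi - vp, sigma) - edge_cdf(vlo - vp, sigma));
      }
    }
    out[p] = acc > 1.0 ? 1.0 : acc;
  }
  return out;
}
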