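#include <Rcpp.h>
using namespace Rcpp;

// Trilinear interpolation of a 3D volume (column-major, dim = c(nx,ny,nz))
// at world points (mm). Voxel i (1-based) is centered at origin + (i-1)*spacing.
// Points outside the convex hull of voxel centers get `fill`.
// [[Rcpp::export]]
NumericVector cpp_interp3(NumericVector vol, IntegerVector dim,
                          NumericVector spacing, NumericVector origin,
                          NumericMatrix pts, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int npts = pts.nrow();
  NumericVector out(npts);
  for (int p = 0; p < npts; ++p) {
    double fx = (pts(p, 0) - origin[0]) / spacing[0];
    double fy = (pts(p, 1) - origin[1]) / spacing[1];
    double fz = (pts(p, 2) - origin[2]) / spacing[2];
    if (fx < 0 || fy < 0 || fz < 0 || fx > nx - 1 || fy > ny - 1 || fz > nz - 1) {
      out[p] = fill;
      continue;
    }
    int ix = (int)std::floor(fx); if (ix > nx - 2) ix = nx > 1 ? nx - 2 : 0;
    int iy = (int)std::floor(fy); if (iy > ny - 2) iy = ny > 1 ? ny - 2 : 0;
    int iz = (int)std::floor(fz); if (iz > nz - 2) iz = nz > 1 ? nz - 2 : 0;
    double tx = fx - ix, ty = fy - iy, tz = fz - iz;
    if (nx == 1) { ix = 0; tx = 0.0; }
    if (ny == 1) { iy = 0; ty = 0.0; }
    if (nz == 1) { iz = 0; tz = 0.0; }
    const int sx = 1, sy = nx, sz = nx * ny;
    const int i000 = ix + iy * sy + iz * sz;
    const int dx = (nx > 1) ? sx : 0, dy = (ny > 1) ? sy : 0, dz = (nz > 1) ? sz : 0;
    double c000 = vol[i000],           c100 = vol[i000 + dx];
    double c010 = vol[i000 + dy],      c110 = vol[i000 + dx + dy];
    double c001 = vol[i000 + dz],      c101 = vol[i000 + dx + dz];
    double c011 = vol[i000 + dy + dz], c111 = vol[i000 + dx + dy + dz];
    double c00 = c000 * (1 - tx) + c100 * tx;
    double c10 = c010 * (1 - tx) + c110 * tx;
    double c01 = c001 * (1 - tx) + c101 * tx;
    double c11 = c011 * (1 - tx) + c111 * tx;
    double c0 = c00 * (1 - ty) + c10 * ty;
    double c1 = c01 * (1 - ty) + c11 * ty;
    out[p] = c0 * (1 - tz) + c1 * tz;
  }
  return out;
}

// Separable 1D convolution along `axis` (0, 1 or 2) with replicate
// boundary handling. Kernel must have odd length.
// [[Rcpp::export]]
NumericVector cpp_sepconv(NumericVector vol, IntegerVector dim,
                          NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int klen = kernel.size(), kh = klen / 2;
  NumericVector out(vol.size());
  const int stride[3] = {1, nx, nx * ny};
  const int n[3] = {nx, ny, nz};
  const int na = n[axis], sa = stride[axis];
  // iterate over all lines along `axis`
  int oa1 = (axis + 1) % 3, oa2 = (axis + 2) % 3;
  for (int j = 0; j < n[oa2]; ++j) {
    for (int i = 0; i < n[oa1]; ++i) {
      const int base = i * stride[oa1] + j * stride[oa2];
      for (int k = 0; k < na; ++k) {
        double acc = 0.0;
        for (int m = 0; m < klen; ++m) {
          int kk = k + m - kh;
          if (kk < 0) kk = 0;
          if (kk > na - 1) kk = na - 1;
          acc += kernel[m] * vol[base + kk * sa];
        }
        out[base + k * sa] = acc;
      }
    }
  }
  return out;
}
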