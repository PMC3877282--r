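#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Voxel accessor; indices outside the grid read as background (0).
static inline double vox(const double *a, int nx, int ny, int nz,
                         int i, int j, int k) {
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0.0;
  return a[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k)];
}

// Trilinear interpolation at a continuous, 0-based, voxel-centered
// coordinate. Points outside the grid blend toward 0 and return exactly 0
// once more than one voxel away from the boundary.
static inline double trilinear(const double *a, int nx, int ny, int nz,
                               double x, double y, double z) {
  if (x <= -1.0 || y <= -1.0 || z <= -1.0 ||
      x >= (double)nx || y >= (double)ny || z >= (double)nz)
    return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double c00 = vox(a, nx, ny, nz, x0, y0, z0) * (1 - fx) +
               vox(a, nx, ny, nz, x0 + 1, y0, z0) * fx;
  double c10 = vox(a, nx, ny, nz, x0, y0 + 1, z0) * (1 - fx) +
               vox(a, nx, ny, nz, x0 + 1, y0 + 1, z0) * fx;
  double c01 = vox(a, nx, ny, nz, x0, y0, z0 + 1) * (1 - fx) +
               vox(a, nx, ny, nz, x0 + 1, y0, z0 + 1) * fx;
  double c11 = vox(a, nx, ny, nz, x0, y0 + 1, z0 + 1) * (1 - fx) +
               vox(a, nx, ny, nz, x0 + 1, y0 + 1, z0 + 1) * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector trilinear_cpp(NumericVector data, IntegerVector dims,
                            NumericMatrix pts) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *a = REAL(data);
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = trilinear(a, nx, ny, nz, pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}

// Cast a batch of rays from one origin. Each ray walks k*step along its
// direction (k = 1, 2, ...) and stops at the first sample classified
// background by the hysteresis rule: foreground if I >= high, background if
// I < low, otherwise inherit the previous sample's class. Samples outside
// the grid are background. Returns (k-1)*step with boundary = true on a
// boundary stop, or max_len with boundary = false when the cap is reached.
// An origin classified background (I0 < low) yields length 0, boundary
// = true for every ray.
// [[Rcpp::export]]
List cast_rays_cpp(NumericVector data, IntegerVector dims,
                   NumericVector origin, NumericMatrix dirs, double step,
                   NumericVector max_len, double high, double low) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *a = REAL(data);
  int n = dirs.nrow();
  NumericVector len(n);
  LogicalVector bnd(n);
  double I0 = trilinear(a, nx, ny, nz, origin[0], origin[1], origin[2]);
  bool fg0 = (I0 >= low);
  for (int i = 0; i < n; ++i) {
    double L = (max_len.size() == 1) ? max_len[0] : max_len[i];
    if (!fg0) { len[i] = 0.0; bnd[i] = true; continue; }
    bool fg = true, boundary = false;
    double out_len = L;
    for (int k = 1; (double)k * step <= L + 1e-9; ++k) {
      double px = origin[0] + k * step * dirs(i, 0);
      double py = origin[1] + k * step * dirs(i, 1);
      double pz = origin[2] + k * step * dirs(i, 2);
      bool inside = (px >= 0.0 && py >= 0.0 && pz >= 0.0 &&
                     px <= nx - 1.0 && py <= ny - 1.0 && pz <= nz - 1.0);
      bool cls;
      if (!inside) {
        cls = false;
      } else {
        double I = trilinear(a, nx, ny, nz, px, py, pz);
        if (I >= high) cls = true;
        else if (I < low) cls = false;
        else cls = fg;
      }
      if (!cls) { out_len = (k - 1) * step; boundary = true; break; }
      fg = cls;
    }
    len[i] = out_len;
    bnd[i] = boundary;
  }
  return List::create(_["length"] = len, _["boundary"] = bnd);
}
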