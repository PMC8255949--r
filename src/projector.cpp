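#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Ray-driven (Joseph-style) parallel-beam projector with a matched adjoint.
//
// Conventions (shared with the R wrappers):
//  - image volume dims (nz, ny, nx), column-major, voxel centres at
//      x = (ix - (nx-1)/2) * vx + cx,  y = (iy - (ny-1)/2) * vy + cy
//    (0-based ix, iy), slices iz mapped one-to-one to detector rows.
//  - sinogram dims (na, nv, nh): angle, vertical, horizontal.
//  - detector coordinate s_j = (j - (nh-1)/2) * ds; the ray through s_j at
//    angle theta (CCW from +x) is { x cos t + y sin t = p }, p = s_j - off,
//    sampled at step h = min(vx, vy) along direction (-sin t, cos t).
//  - forward gathers bilinear samples times h; adjoint scatters the exact
//    transpose weights, so <Au, z> == <u, A^T z> to rounding.

static inline void ray_setup(double p, double ct, double st,
                             double T, double h, int &nt,
                             double &bx, double &by,
                             double &dx, double &dy) {
  nt = 2 * (int)std::ceil(T / h) + 1;
  double t0 = -0.5 * (nt - 1) * h;
  bx = p * ct - t0 * st;
  by = p * st + t0 * ct;
  dx = -st * h;
  dy = ct * h;
}

// restrict the sample index range to the part of the ray that can touch the
// interpolation support (grid bounding box plus one voxel margin); pure
// skipping of zero-weight samples, so results are bit-identical
static inline void clip_range(double b0, double d, double lo, double hi,
                              int nt, int &k0, int &k1) {
  if (d == 0.0) {
    if (b0 < lo || b0 > hi) { k0 = 1; k1 = 0; }
    return;
  }
  double ta = (lo - b0) / d, tb = (hi - b0) / d;
  if (ta > tb) std::swap(ta, tb);
  if (tb < 0.0 || ta > (double)(nt - 1)) { k0 = 1; k1 = 0; return; }
  int a = (ta <= 0.0) ? 0 : (int)std::ceil(ta);        // clamp before cast:
  int b = (tb >= (double)(nt - 1)) ? nt - 1             // huge ta/tb from
          : (int)std::floor(tb);                        // near-zero d overflow
  if (a > k0) k0 = a;
  if (b < k1) k1 = b;
}

// [[Rcpp::export]]
NumericVector radon_forward_cpp(NumericVector img,
                                int nz, int ny, int nx,
                                double vx, double vy,
                                double cx, double cy,
                                NumericVector angles,
                                int nh, double ds, double offset) {
  const int na = angles.size();
  const int nv = nz;
  NumericVector sino(static_cast<R_xlen_t>(na) * nv * nh);
  const double h = std::min(vx, vy);
  const double T = 0.5 * std::hypot(nx * vx, ny * vy) +
                   std::abs(cx) + std::abs(cy) + h;
  const double x0 = cx - 0.5 * (nx - 1) * vx;
  const double y0 = cy - 0.5 * (ny - 1) * vy;

  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int j = 0; j < nh; ++j) {
      const double p = (j - 0.5 * (nh - 1)) * ds - offset;
      int nt; double bx, by, dx, dy;
      ray_setup(p, ct, st, T, h, nt, bx, by, dx, dy);
      int k0 = 0, k1 = nt - 1;
      clip_range(bx, dx, x0 - vx, x0 + nx * vx, nt, k0, k1);
      clip_range(by, dy, y0 - vy, y0 + ny * vy, nt, k0, k1);
      // accumulate per z-slice
      for (int t = k0; t <= k1; ++t) {
        const double gx = (bx + t * dx - x0) / vx;
        const double gy = (by + t * dy - y0) / vy;
        const int ix0 = (int)std::floor(gx);
        const int iy0 = (int)std::floor(gy);
        if (ix0 < -1 || ix0 > nx - 1 || iy0 < -1 || iy0 > ny - 1) continue;
        const double wx = gx - ix0, wy = gy - iy0;
        const double w00 = (1 - wx) * (1 - wy), w10 = wx * (1 - wy),
                     w01 = (1 - wx) * wy,       w11 = wx * wy;
        for (int iz = 0; iz < nz; ++iz) {
          double acc = 0.0;
          if (iy0 >= 0) {
            if (ix0 >= 0)
              acc += w00 * img[iz + (R_xlen_t)nz * (iy0 + (R_xlen_t)ny * ix0)];
            if (ix0 + 1 <= nx - 1)
              acc += w10 * img[iz + (R_xlen_t)nz * (iy0 + (R_xlen_t)ny * (ix0 + 1))];
          }
          if (iy0 + 1 <= ny - 1) {
            if (ix0 >= 0)
              acc += w01 * img[iz + (R_xlen_t)nz * ((iy0 + 1) + (R_xlen_t)ny * ix0)];
            if (ix0 + 1 <= nx - 1)
              acc += w11 * img[iz + (R_xlen_t)nz * ((iy0 + 1) + (R_xlen_t)ny * (ix0 + 1))];
          }
          sino[a + (R_xlen_t)na * (iz + (R_xlen_t)nv * j)] += acc * h;
        }
      }
    }
  }
  return sino;
}

// [[Rcpp::export]]
NumericVector back_project_cpp(NumericVector sino,
                               int na, int nv, int nh,
                               double ds, double offset,
                               NumericVector angles,
                               int nz, int ny, int nx,
                               double vx, double vy,
                               double cx, double cy) {
  NumericVector img(static_cast<R_xlen_t>(nz) * ny * nx);
  const double h = std::min(vx, vy);
  const double T = 0.5 * std::hypot(nx * vx, ny * vy) +
                   std::abs(cx) + std::abs(cy) + h;
  const double x0 = cx - 0.5 * (nx - 1) * vx;
  const double y0 = cy - 0.5 * (ny - 1) * vy;

  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int j = 0; j < nh; ++j) {
      const double p = (j - 0.5 * (nh - 1)) * ds - offset;
      int nt; double bx, by, dx, dy;
      ray_setup(p, ct, st, T, h, nt, bx, by, dx, dy);
      int k0 = 0, k1 = nt - 1;
      clip_range(bx, dx, x0 - vx, x0 + nx * vx, nt, k0, k1);
      clip_range(by, dy, y0 - vy, y0 + ny * vy, nt, k0, k1);
      for (int t = k0; t <= k1; ++t) {
        const double gx = (bx + t * dx - x0) / vx;
        const double gy = (by + t * dy - y0) / vy;
        const int ix0 = (int)std::floor(gx);
        const int iy0 = (int)std::floor(gy);
        if (ix0 < -1 || ix0 > nx - 1 || iy0 < -1 || iy0 > ny - 1) continue;
        const double wx = gx - ix0, wy = gy - iy0;
        const double w00 = (1 - wx) * (1 - wy), w10 = wx * (1 - wy),
                     w01 = (1 - wx) * wy,       w11 = wx * wy;
        for (int iz = 0; iz < nz; ++iz) {
          const double s = sino[a + (R_xlen_t)na * (iz + (R_xlen_t)nv * j)] * h;
          if (s == 0.0) continue;
          if (iy0 >= 0) {
            if (ix0 >= 0)
              img[iz + (R_xlen_t)nz * (iy0 + (R_xlen_t)ny * ix0)] += w00 * s;
            if (ix0 + 1 <= nx - 1)
              img[iz + (R_xlen_t)nz * (iy0 + (R_xlen_t)ny * (ix0 + 1))] += w10 * s;
          }
          if (iy0 + 1 <= ny - 1) {
            if (ix0 >= 0)
              img[iz + (R_xlen_t)nz * ((iy0 + 1) + (R_xlen_t)ny * ix0)] += w01 * s;
            if (ix0 + 1 <= nx - 1)
              img[iz + (R_xlen_t)nz * ((iy0 + 1) + (R_xlen_t)ny * (ix0 + 1))] += w11 * s;
          }
        }
      }
    }
  }
  return img;
}
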