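#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Single-axis parallel-beam projector. Volume layout (y, x, z) column-major,
// tilt axis y, beam along +z at 0 degrees, rotation CCW about +y. One ray per
// detector bin, sampled at unit-voxel steps; bilinear (or nearest) weights in
// the (x, z) plane. The adjoint scatters the exact transpose of the gather
// weights, so <Au, v> == <u, At v> up to rounding.

static inline int nsamp_for(int nx, int nz) {
  int n = (int)std::ceil(std::sqrt((double)nx * nx + (double)nz * nz));
  if (n % 2 == 0) n += 1; // odd: integer sample offsets symmetric about 0
  return n;
}

// interp: 0 = linear, 1 = nearest (ties resolved by floor(x + 0.5))
// [[Rcpp::export]]
NumericVector cppForwardProject(const NumericVector& vol, const IntegerVector& dims,
                                const NumericVector& anglesDeg, int interp) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const int na = anglesDeg.size();
  NumericVector out((R_xlen_t)na * ny * nx);
  const double cx = 0.5 * (nx - 1), cz = 0.5 * (nz - 1);
  const int ns = nsamp_for(nx, nz), half = (ns - 1) / 2;
  const double* v = vol.begin();
  double* o = out.begin();
  for (int a = 0; a < na; ++a) {
    const double th = anglesDeg[a] * M_PI / 180.0;
    const double c = std::cos(th), s = std::sin(th);
    for (int i = 0; i < nx; ++i) {
      const double t = i - cx;
      double* orow = o + a + (R_xlen_t)na * ny * i; // + na*y inside
      for (int j = 0; j < ns; ++j) {
        const double sj = j - half;
        const double x = cx + t * c - sj * s;
        const double z = cz + t * s + sj * c;
        if (interp == 1) {
          const int ix = (int)std::floor(x + 0.5);
          const int iz = (int)std::floor(z + 0.5);
          if (ix < 0 || ix >= nx || iz < 0 || iz >= nz) continue;
          const double* vcol = v + (R_xlen_t)ny * (ix + (R_xlen_t)nx * iz);
          for (int y = 0; y < ny; ++y) orow[(R_xlen_t)na * y] += vcol[y];
        } else {
          const int x0 = (int)std::floor(x), z0 = (int)std::floor(z);
          const double fx = x - x0, fz = z - z0;
          const double w00 = (1 - fx) * (1 - fz), w10 = fx * (1 - fz);
          const double w01 = (1 - fx) * fz, w11 = fx * fz;
          const bool x0i = (x0 >= 0 && x0 < nx), x1i = (x0 + 1 >= 0 && x0 + 1 < nx);
          const bool z0i = (z0 >= 0 && z0 < nz), z1i = (z0 + 1 >= 0 && z0 + 1 < nz);
          if (!((x0i || x1i) && (z0i || z1i))) continue;
          for (int y = 0; y < ny; ++y) {
            double acc = 0.0;
            const R_xlen_t base = y;
            if (x0i && z0i) acc += w00 * v[base + (R_xlen_t)ny * (x0 + (R_xlen_t)nx * z0)];
            if (x1i && z0i) acc += w10 * v[base + (R_xlen_t)ny * (x0 + 1 + (R_xlen_t)nx * z0)];
            if (x0i && z1i) acc += w01 * v[base + (R_xlen_t)ny * (x0 + (R_xlen_t)nx * (z0 + 1))];
            if (x1i && z1i) acc += w11 * v[base + (R_xlen_t)ny * (x0 + 1 + (R_xlen_t)nx * (z0 + 1))];
            orow[(R_xlen_t)na * y] += acc;
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cppBackProject(const NumericVector& sino, const IntegerVector& dims,
                             const NumericVector& anglesDeg, int interp) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const int na = anglesDeg.size();
  NumericVector out((R_xlen_t)ny * nx * nz);
  const double cx = 0.5 * (nx - 1), cz = 0.5 * (nz - 1);
  const int ns = nsamp_for(nx, nz), half = (ns - 1) / 2;
  const double* b = sino.begin();
  double* v = out.begin();
  for (int a = 0; a < na; ++a) {
    const double th = anglesDeg[a] * M_PI / 180.0;
    const double c = std::cos(th), s = std::sin(th);
    for (int i = 0; i < nx; ++i) {
      const double t = i - cx;
      const double* brow = b + a + (R_xlen_t)na * ny * i;
      for (int j = 0; j < ns; ++j) {
        const double sj = j - half;
        const double x = cx + t * c - sj * s;
        const double z = cz + t * s + sj * c;
        if (interp == 1) {
          const int ix = (int)std::floor(x + 0.5);
          const int iz = (int)std::floor(z + 0.5);
          if (ix < 0 || ix >= nx || iz < 0 || iz >= nz) continue;
          double* vcol = v + (R_xlen_t)ny * (ix + (R_xlen_t)nx * iz);
          for (int y = 0; y < ny; ++y) vcol[y] += brow[(R_xlen_t)na * y];
        } else {
          const int x0 = (int)std::floor(x), z0 = (int)std::floor(z);
          const double fx = x - x0, fz = z - z0;
          const double w00 = (1 - fx) * (1 - fz), w10 = fx * (1 - fz);
          const double w01 = (1 - fx) * fz, w11 = fx * fz;
          const bool x0i = (x0 >= 0 && x0 < nx), x1i = (x0 + 1 >= 0 && x0 + 1 < nx);
          const bool z0i = (z0 >= 0 && z0 < nz), z1i = (z0 + 1 >= 0 && z0 + 1 < nz);
          if (!((x0i || x1i) && (z0i || z1i))) continue;
          for (int y = 0; y < ny; ++y) {
            const double by = brow[(R_xlen_t)na * y];
            if (by == 0.0) continue;
            if (x0i && z0i) v[y + (R_xlen_t)ny * (x0 + (R_xlen_t)nx * z0)] += w00 * by;
            if (x1i && z0i) v[y + (R_xlen_t)ny * (x0 + 1 + (R_xlen_t)nx * z0)] += w10 * by;
            if (x0i && z1i) v[y + (R_xlen_t)ny * (x0 + (R_xlen_t)nx * (z0 + 1))] += w01 * by;
            if (x1i && z1i) v[y + (R_xlen_t)ny * (x0 + 1 + (R_xlen_t)nx * (z0 + 1))] += w11 * by;
          }
        }
      }
    }
  }
  return out;
}
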