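// Resampling of a 3D scalar grid through a 4x4 voxel->voxel affine map.
// `m` maps 0-based destination voxel indices to 0-based continuous source
// voxel coordinates. Out-of-field destination voxels get `fill` and
// valid = FALSE. Trilinear requires the full 8-neighbour support in bounds.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".resample_affine")]]
List resample_affine(NumericVector src, NumericMatrix m, IntegerVector odim,
                     int method, double fill) {
  IntegerVector d = src.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const int ox = odim[0], oy = odim[1], oz = odim[2];
  const size_t no = (size_t)ox * oy * oz;
  NumericVector out(no, fill);
  LogicalVector valid(no, false);
  const double *ps = REAL(src);
  double *po = REAL(out);
  int *pv = LOGICAL(valid);
  const double m00 = m(0, 0), m01 = m(0, 1), m02 = m(0, 2), m03 = m(0, 3);
  const double m10 = m(1, 0), m11 = m(1, 1), m12 = m(1, 2), m13 = m(1, 3);
  const double m20 = m(2, 0), m21 = m(2, 1), m22 = m(2, 2), m23 = m(2, 3);
  size_t j = 0;
  for (int z = 0; z < oz; ++z)
    for (int y = 0; y < oy; ++y)
      for (int x = 0; x < ox; ++x, ++j) {
        const double sx = m00 * x + m01 * y + m02 * z + m03;
        const double sy = m10 * x + m11 * y + m12 * z + m13;
        const double sz = m20 * x + m21 * y + m22 * z + m23;
        if (method == 1) {  // nearest
          const int ix = (int)std::lround(sx);
          const int iy = (int)std::lround(sy);
          const int iz = (int)std::lround(sz);
          if (ix >= 0 && ix < nx && iy >= 0 && iy < ny && iz >= 0 && iz < nz) {
            po[j] = ps[(size_t)iz * nx * ny + (size_t)iy * nx + ix];
            pv[j] = true;
          }
        } else {  // trilinear
          // clamp the cell index so exact upper-boundary coordinates stay
          // inside the grid (fx then equals 1)
          int ix = (int)std::floor(sx);
          int iy = (int)std::floor(sy);
          int iz = (int)std::floor(sz);
          if (ix == nx - 1 && sx == (double)(nx - 1)) --ix;
          if (iy == ny - 1 && sy == (double)(ny - 1)) --iy;
          if (iz == nz - 1 && sz == (double)(nz - 1)) --iz;
          if (ix >= 0 && ix + 1 < nx && iy >= 0 && iy + 1 < ny && iz >= 0 &&
              iz + 1 < nz) {
            const double fx = sx - ix, fy = sy - iy, fz = sz - iz;
            double v = 0.0;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx) {
                  const double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                                   (dz ? fz : 1 - fz);
                  v += w * ps[(size_t)(iz + dz) * nx * ny +
                              (size_t)(iy + dy) * nx + (ix + dx)];
                }
            po[j] = v;
            pv[j] = true;
          }
        }
      }
  out.attr("dim") = odim;
  valid.attr("dim") = odim;
  return List::create(_["values"] = out, _["valid"] = valid);
}

// Trilinear sampling of selected destination voxels only (registration
// similarity support): idx holds 0-based destination voxel coordinates,
// n x 3; m maps them to continuous source voxel coordinates.
// [[Rcpp::export(name = ".resample_points")]]
List resample_points(NumericVector src, NumericMatrix m, IntegerMatrix idx) {
  IntegerVector d = src.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const int n = idx.nrow();
  NumericVector out(n);
  LogicalVector valid(n, false);
  const double *ps = REAL(src);
  const double m00 = m(0, 0), m01 = m(0, 1), m02 = m(0, 2), m03 = m(0, 3);
  const double m10 = m(1, 0), m11 = m(1, 1), m12 = m(1, 2), m13 = m(1, 3);
  const double m20 = m(2, 0), m21 = m(2, 1), m22 = m(2, 2), m23 = m(2, 3);
  for (int j = 0; j < n; ++j) {
    const double x = idx(j, 0), y = idx(j, 1), z = idx(j, 2);
    const double sx = m00 * x + m01 * y + m02 * z + m03;
    const double sy = m10 * x + m11 * y + m12 * z + m13;
    const double sz = m20 * x + m21 * y + m22 * z + m23;
    int ix = (int)std::floor(sx);
    int iy = (int)std::floor(sy);
    int iz = (int)std::floor(sz);
    if (ix == nx - 1 && sx == (double)(nx - 1)) --ix;
    if (iy == ny - 1 && sy == (double)(ny - 1)) --iy;
    if (iz == nz - 1 && sz == (double)(nz - 1)) --iz;
    if (ix >= 0 && ix + 1 < nx && iy >= 0 && iy + 1 < ny && iz >= 0 &&
        iz + 1 < nz) {
      const double fx = sx - ix, fy = sy - iy, fz = sz - iz;
      double v = 0.0;
      for (int dz = 0; dz < 2; ++dz)
        for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            const double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                             (dz ? fz : 1 - fz);
            v += w * ps[(size_t)(iz + dz) * nx * ny + (size_t)(iy + dy) * nx +
                        (ix + dx)];
          }
      out[j] = v;
      valid[j] = true;
    }
  }
  return List::create(_["values"] = out, _["valid"] = valid);
}

// 2x mean-pooling downsample (registration pyramid); truncates odd trailing
// voxels.
// [[Rcpp::export(name = ".downsample2_mean")]]
NumericVector downsample2_mean(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  NumericVector y((size_t)ox * oy * oz);
  const double *px = REAL(x);
  double *py = REAL(y);
  size_t j = 0;
  for (int z = 0; z < oz; ++z)
    for (int yy = 0; yy < oy; ++yy)
      for (int xx = 0; xx < ox; ++xx, ++j) {
        double s = 0;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx)
              s += px[(size_t)(2 * z + dz) * nx * ny +
                      (size_t)(2 * yy + dy) * nx + (2 * xx + dx)];
        py[j] = s / 8.0;
      }
  y.attr("dim") = IntegerVector::create(ox, oy, oz);
  return y;
}

// Separable Gaussian blur, sigma per axis in voxels; truncated at 3 sigma and
// renormalised at the borders.
// [[Rcpp::export(name = ".gaussian_blur3d")]]
NumericVector gaussian_blur3d(NumericVector x, NumericVector sigma) {
  IntegerVector d = x.attr("dim");
  const int n[3] = {d[0], d[1], d[2]};
  std::vector<double> buf(REAL(x), REAL(x) + x.size());
  std::vector<double> tmp(x.size());
  const size_t stride[3] = {1, (size_t)n[0], (size_t)n[0] * n[1]};
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma[ax];
    if (s <= 0) continue;
    const int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    for (int i = -r; i <= r; ++i) k[i + r] = std::exp(-0.5 * i * i / (s * s));
    const int len = n[ax];
    const size_t st = stride[ax];
    const size_t nlines = x.size() / len;
    for (size_t line = 0; line < nlines; ++line) {
      // decompose line index into the two fixed axes
      size_t rem = line, base = 0;
      for (int a = 0; a < 3; ++a) {
        if (a == ax) continue;
        base += (rem % n[a]) * stride[a];
        rem /= n[a];
      }
      for (int i = 0; i < len; ++i) {
        double acc = 0, wsum = 0;
        const int lo = std::max(-r, -i), hi = std::min(r, len - 1 - i);
        for (int o = lo; o <= hi; ++o) {
          acc += k[o + r] * buf[base + (size_t)(i + o) * st];
          wsum += k[o + r];
        }
        tmp[base + (size_t)i * st] = acc / wsum;
      }
    }
    buf.swap(tmp);
  }
  NumericVector out(buf.begin(), buf.end());
  out.attr("dim") = d;
  return out;
}
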