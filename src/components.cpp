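// Connected components (26- or 6-connectivity), border flood fill for hole
// filling, and binary morphology with a spacing-scaled ellipsoidal element.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(NumericVector mask, int connectivity) {
  IntegerVector d = mask.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const size_t n = (size_t)nx * ny * nz;
  const double *pm = REAL(mask);
  IntegerVector lab(n, 0);
  int *pl = INTEGER(lab);
  std::vector<size_t> stack;
  int next = 0;
  for (size_t i = 0; i < n; ++i) {
    if (pm[i] == 0 || pl[i] != 0) continue;
    ++next;
    pl[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      const size_t cur = stack.back();
      stack.pop_back();
      const int cz = (int)(cur / ((size_t)nx * ny));
      const int cy = (int)((cur / nx) % ny);
      const int cx = (int)(cur % nx);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) > 1)
              continue;
            const int x = cx + dx, y = cy + dy, z = cz + dz;
            if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
              continue;
            const size_t j = (size_t)z * nx * ny + (size_t)y * nx + x;
            if (pm[j] != 0 && pl[j] == 0) {
              pl[j] = next;
              stack.push_back(j);
            }
          }
    }
  }
  lab.attr("dim") = d;
  return lab;
}

// Fill internal cavities: 6-connected background flood fill from the border;
// unreached background becomes foreground.
// [[Rcpp::export(name = ".fill_holes")]]
NumericVector fill_holes(NumericVector mask) {
  IntegerVector d = mask.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const size_t n = (size_t)nx * ny * nz;
  const double *pm = REAL(mask);
  std::vector<char> outside(n, 0);
  std::vector<size_t> stack;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (x != 0 && x != nx - 1 && y != 0 && y != ny - 1 && z != 0 &&
            z != nz - 1)
          continue;
        const size_t i = (size_t)z * nx * ny + (size_t)y * nx + x;
        if (pm[i] == 0 && !outside[i]) {
          outside[i] = 1;
          stack.push_back(i);
        }
      }
  const int off[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
                         {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
  while (!stack.empty()) {
    const size_t cur = stack.back();
    stack.pop_back();
    const int cz = (int)(cur / ((size_t)nx * ny));
    const int cy = (int)((cur / nx) % ny);
    const int cx = (int)(cur % nx);
    for (int k = 0; k < 6; ++k) {
      const int x = cx + off[k][0], y = cy + off[k][1], z = cz + off[k][2];
      if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
      const size_t j = (size_t)z * nx * ny + (size_t)y * nx + x;
      if (pm[j] == 0 && !outside[j]) {
        outside[j] = 1;
        stack.push_back(j);
      }
    }
  }
  NumericVector out(n);
  double *po = REAL(out);
  for (size_t i = 0; i < n; ++i) po[i] = (pm[i] != 0 || !outside[i]) ? 1.0 : 0.0;
  out.attr("dim") = d;
  return out;
}

static std::vector<std::array<int, 3>> ball_offsets(double radius_mm,
                                                    NumericVector spacing) {
  std::vector<std::array<int, 3>> off;
  const int rx = (int)std::floor(radius_mm / spacing[0]);
  const int ry = (int)std::floor(radius_mm / spacing[1]);
  const int rz = (int)std::floor(radius_mm / spacing[2]);
  for (int dz = -rz; dz <= rz; ++dz)
    for (int dy = -ry; dy <= ry; ++dy)
      for (int dx = -rx; dx <= rx; ++dx) {
        const double r2 =
            std::pow(dx * spacing[0], 2) + std::pow(dy * spacing[1], 2) +
            std::pow(dz * spacing[2], 2);
        if (r2 <= radius_mm * radius_mm) off.push_back({dx, dy, dz});
      }
  return off;
}

// [[Rcpp::export(name = ".morph_ball")]]
NumericVector morph_ball(NumericVector mask, double radius_mm,
                         NumericVector spacing, bool dilate) {
  IntegerVector d = mask.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const size_t n = (size_t)nx * ny * nz;
  const double *pm = REAL(mask);
  NumericVector out(n);
  double *po = REAL(out);
  const auto off = ball_offsets(radius_mm, spacing);
  size_t i = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++i) {
        bool hit = dilate ? false : true;
        for (const auto &o : off) {
          const int xx = x + o[0], yy = y + o[1], zz = z + o[2];
          const bool inb =
              xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz;
          const double v =
              inb ? pm[(size_t)zz * nx * ny + (size_t)yy * nx + xx] : 0.0;
          if (dilate) {
            if (v != 0) { hit = true; break; }
          } else {
            if (v == 0) { hit = false; break; }
          }
        }
        po[i] = hit ? 1.0 : 0.0;
      }
  out.attr("dim") = d;
  return out;
}

// Surface voxels: foreground with at least one 6-neighbour background voxel
// (grid boundary counts as background). Returns 0-based voxel indices, n x 3.
// [[Rcpp::export(name = ".surface_voxels")]]
IntegerMatrix surface_voxels(NumericVector mask) {
  IntegerVector d = mask.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const double *pm = REAL(mask);
  std::vector<std::array<int, 3>> surf;
  const int off[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
                         {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
  size_t i = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++i) {
        if (pm[i] == 0) continue;
        bool border = false;
        for (int k = 0; k < 6 && !border; ++k) {
          const int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz ||
              pm[(size_t)zz * nx * ny + (size_t)yy * nx + xx] == 0)
            border = true;
        }
        if (border) surf.push_back({x, y, z});
      }
  IntegerMatrix out(surf.size(), 3);
  for (size_t r = 0; r < surf.size(); ++r)
    for (int c = 0; c < 3; ++c) out(r, c) = surf[r][c];
  return out;
}

// Sum over rows of `a` of the minimum Euclidean distance to any row of `b`
// (coordinates already in mm).
// [[Rcpp::export(name = ".sum_min_dist")]]
double sum_min_dist(NumericMatrix a, NumericMatrix b) {
  double total = 0.0;
  for (int i = 0; i < a.nrow(); ++i) {
    double best = R_PosInf;
    const double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    for (int j = 0; j < b.nrow(); ++j) {
      const double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    total += std::sqrt(best);
  }
  return total;
}
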