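// 2x2x2 max pooling and nearest-neighbour upsampling for (X,Y,Z,C) tensors.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".maxpool3d_forward")]]
List maxpool3d_forward(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2], nc = d[3];
  if (nx % 2 || ny % 2 || nz % 2) stop("pooling needs even spatial dims");
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const size_t ni = (size_t)nx * ny * nz, no = (size_t)ox * oy * oz;
  NumericVector y(no * nc);
  IntegerVector arg(no * nc);
  const double *px = REAL(x);
  double *py = REAL(y);
  int *pa = INTEGER(arg);
  for (int c = 0; c < nc; ++c) {
    const double *xc = px + (size_t)c * ni;
    size_t j = (size_t)c * no;
    for (int z = 0; z < oz; ++z)
      for (int yy = 0; yy < oy; ++yy)
        for (int xx = 0; xx < ox; ++xx, ++j) {
          double best = -std::numeric_limits<double>::infinity();
          size_t besti = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                size_t i = (size_t)(2 * z + dz) * nx * ny +
                           (size_t)(2 * yy + dy) * nx + (2 * xx + dx);
                if (xc[i] > best) { best = xc[i]; besti = i; }
              }
          py[j] = best;
          pa[j] = (int)((size_t)c * ni + besti);  // linear index into x
        }
  }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  arg.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool3d_backward")]]
NumericVector maxpool3d_backward(NumericVector dy, IntegerVector argmax,
                                 IntegerVector xdim) {
  const size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  double *pdx = REAL(dx);
  const double *pdy = REAL(dy);
  const int *pa = INTEGER(argmax);
  for (R_xlen_t j = 0; j < dy.size(); ++j) pdx[pa[j]] += pdy[j];
  dx.attr("dim") = xdim;
  return dx;
}

// [[Rcpp::export(name = ".upsample3d_forward")]]
NumericVector upsample3d_forward(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2], nc = d[3];
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  const size_t ni = (size_t)nx * ny * nz, no = (size_t)ox * oy * oz;
  NumericVector y(no * nc);
  const double *px = REAL(x);
  double *py = REAL(y);
  for (int c = 0; c < nc; ++c) {
    const double *xc = px + (size_t)c * ni;
    double *yc = py + (size_t)c * no;
    size_t j = 0;
    for (int z = 0; z < oz; ++z)
      for (int yy = 0; yy < oy; ++yy)
        for (int xx = 0; xx < ox; ++xx, ++j)
          yc[j] = xc[(size_t)(z / 2) * nx * ny + (size_t)(yy / 2) * nx + xx / 2];
  }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  return y;
}

// [[Rcpp::export(name = ".upsample3d_backward")]]
NumericVector upsample3d_backward(NumericVector dy) {
  IntegerVector d = dy.attr("dim");
  const int ox = d[0], oy = d[1], oz = d[2], nc = d[3];
  const int nx = ox / 2, ny = oy / 2, nz = oz / 2;
  const size_t ni = (size_t)nx * ny * nz, no = (size_t)ox * oy * oz;
  NumericVector dx(ni * nc);
  double *pdx = REAL(dx);
  const double *pdy = REAL(dy);
  for (int c = 0; c < nc; ++c) {
    const double *yc = pdy + (size_t)c * no;
    double *xc = pdx + (size_t)c * ni;
    size_t j = 0;
    for (int z = 0; z < oz; ++z)
      for (int yy = 0; yy < oy; ++yy)
        for (int xx = 0; xx < ox; ++xx, ++j)
          xc[(size_t)(z / 2) * nx * ny + (size_t)(yy / 2) * nx + xx / 2] += yc[j];
  }
  dx.attr("dim") = IntegerVector::create(nx, ny, nz, nc);
  return dx;
}
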