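// 3x3x3 same-padding convolution for channel-last tensors, via vol2col + BLAS.
//
// Tensor layout (column-major, as produced by R `array`):
//   activations: dim c(X, Y, Z, C)
//   weights:     dim c(3, 3, 3, Cin, Cout)
// so a weight element (kx,ky,kz,ci,co) sits at linear index
//   kx + 3*ky + 9*kz + 27*ci + 27*Cin*co
// and the vol2col row index must follow the same ordering.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline size_t vox(int x, int y, int z, int nx, int ny) {
  return (size_t)z * nx * ny + (size_t)y * nx + x;
}

static arma::mat vol2col(const double *x, int nx, int ny, int nz, int cin) {
  const size_t n = (size_t)nx * ny * nz;
  arma::mat K(27 * cin, n);
  size_t j = 0;
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix, ++j) {
        double *col = K.colptr(j);
        const bool interior = ix > 0 && ix < nx - 1 && iy > 0 &&
                              iy < ny - 1 && iz > 0 && iz < nz - 1;
        if (interior) {
          for (int c = 0; c < cin; ++c) {
            const double *base = x + (size_t)c * n + vox(ix, iy, iz, nx, ny);
            double *cr = col + 27 * c;
            for (int kz = -1; kz <= 1; ++kz) {
              const double *pz = base + (ptrdiff_t)kz * nx * ny;
              for (int ky = -1; ky <= 1; ++ky) {
                const double *py = pz + (ptrdiff_t)ky * nx;
                cr[0] = py[-1];
                cr[1] = py[0];
                cr[2] = py[1];
                cr += 3;
              }
            }
          }
        } else {
          for (int c = 0; c < cin; ++c) {
            const double *xc = x + (size_t)c * n;
            int r = 27 * c;
            for (int kz = -1; kz <= 1; ++kz) {
              const int z = iz + kz;
              for (int ky = -1; ky <= 1; ++ky) {
                const int y = iy + ky;
                for (int kx = -1; kx <= 1; ++kx, ++r) {
                  const int xx = ix + kx;
                  col[r] = (xx >= 0 && xx < nx && y >= 0 && y < ny &&
                            z >= 0 && z < nz)
                               ? xc[vox(xx, y, z, nx, ny)]
                               : 0.0;
                }
              }
            }
          }
        }
      }
  return K;
}

static void col2vol(const arma::mat &K, double *dx, int nx, int ny, int nz,
                    int cin) {
  const size_t n = (size_t)nx * ny * nz;
  std::fill(dx, dx + n * cin, 0.0);
  size_t j = 0;
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix, ++j) {
        const double *col = K.colptr(j);
        const bool interior = ix > 0 && ix < nx - 1 && iy > 0 &&
                              iy < ny - 1 && iz > 0 && iz < nz - 1;
        if (interior) {
          for (int c = 0; c < cin; ++c) {
            double *base = dx + (size_t)c * n + vox(ix, iy, iz, nx, ny);
            const double *cr = col + 27 * c;
            for (int kz = -1; kz <= 1; ++kz) {
              double *pz = base + (ptrdiff_t)kz * nx * ny;
              for (int ky = -1; ky <= 1; ++ky) {
                double *py = pz + (ptrdiff_t)ky * nx;
                py[-1] += cr[0];
                py[0] += cr[1];
                py[1] += cr[2];
                cr += 3;
              }
            }
          }
        } else {
          for (int c = 0; c < cin; ++c) {
            double *xc = dx + (size_t)c * n;
            int r = 27 * c;
            for (int kz = -1; kz <= 1; ++kz) {
              const int z = iz + kz;
              for (int ky = -1; ky <= 1; ++ky) {
                const int y = iy + ky;
                for (int kx = -1; kx <= 1; ++kx, ++r) {
                  const int xx = ix + kx;
                  if (xx >= 0 && xx < nx && y >= 0 && y < ny && z >= 0 &&
                      z < nz)
                    xc[vox(xx, y, z, nx, ny)] += col[r];
                }
              }
            }
          }
        }
      }
}

// [[Rcpp::export(name = ".conv3d_forward")]]
NumericVector conv3d_forward(NumericVector x, NumericVector w,
                             NumericVector b) {
  IntegerVector dx = x.attr("dim");
  IntegerVector dw = w.attr("dim");
  const int nx = dx[0], ny = dx[1], nz = dx[2], cin = dx[3];
  const int cout = dw[4];
  if (dw[3] != cin) stop("weight Cin does not match input channels");
  const size_t n = (size_t)nx * ny * nz;

  arma::mat K = vol2col(REAL(x), nx, ny, nz, cin);
  arma::mat W(const_cast<double *>(REAL(w)), 27 * cin, cout, false, true);
  arma::mat Y = K.t() * W;  // n x cout, matches (X,Y,Z,Cout) layout
  for (int co = 0; co < cout; ++co) Y.col(co) += b[co];

  NumericVector out(n * cout);
  std::copy(Y.memptr(), Y.memptr() + n * cout, REAL(out));
  out.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
  return out;
}

// [[Rcpp::export(name = ".conv3d_backward")]]
List conv3d_backward(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector dx_ = x.attr("dim");
  IntegerVector dw_ = w.attr("dim");
  const int nx = dx_[0], ny = dx_[1], nz = dx_[2], cin = dx_[3];
  const int cout = dw_[4];
  const size_t n = (size_t)nx * ny * nz;

  arma::mat K = vol2col(REAL(x), nx, ny, nz, cin);
  arma::mat W(const_cast<double *>(REAL(w)), 27 * cin, cout, false, true);
  arma::mat dY(const_cast<double *>(REAL(dy)), n, cout, false, true);

  arma::mat dW = K * dY;            // 27*cin x cout
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat dK = W * dY.t();        // 27*cin x n

  NumericVector dXout(n * cin);
  col2vol(dK, REAL(dXout), nx, ny, nz, cin);
  dXout.attr("dim") = IntegerVector::create(nx, ny, nz, cin);

  NumericVector dWout(27 * (size_t)cin * cout);
  std::copy(dW.memptr(), dW.memptr() + dW.n_elem, REAL(dWout));
  dWout.attr("dim") = IntegerVector::create(3, 3, 3, cin, cout);

  return List::create(_["dx"] = dXout, _["dw"] = dWout,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
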