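// 3D convolution / pooling / upsampling kernels for the detection UNet.
// Tensors are R arrays of dim (X, Y, Z, C), column-major, so x is the
// fastest index. Convolutions are 3x3x3, stride 1, zero ("same") padding,
// computed per z-slice as im2col + GEMM; the backward pass reuses the same
// column matrices (col^T * gy for the weight gradient, gy * W^T scattered
// back for the input gradient).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat build_col(const double* x, int X, int Y, int Z,
                                  int Cin, int z) {
  // rows: X*Y output positions of slice z; cols: 27*Cin taps
  arma::mat col(X * Y, 27 * Cin, arma::fill::zeros);
  const long plane = (long)X * Y;
  const long vol = plane * Z;
  for (int ci = 0; ci < Cin; ++ci) {
    for (int kz = 0; kz < 3; ++kz) {
      int zz = z + kz - 1;
      if (zz < 0 || zz >= Z) continue;
      for (int ky = 0; ky < 3; ++ky) {
        for (int kx = 0; kx < 3; ++kx) {
          int c = kx + 3 * (ky + 3 * (kz + 3 * ci));
          double* dst = col.colptr(c);
          const double* src = x + (long)ci * vol + (long)zz * plane;
          for (int y = 0; y < Y; ++y) {
            int yy = y + ky - 1;
            if (yy < 0 || yy >= Y) continue;
            // output x range with valid input x+kx-1
            int x0 = std::max(0, 1 - kx);
            int x1 = std::min(X, X + 1 - kx);
            const double* s = src + (long)yy * X + (x0 + kx - 1);
            double* dp = dst + (long)y * X + x0;
            for (int x_ = x0; x_ < x1; ++x_) *dp++ = *s++;
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
NumericVector conv3_fwd(NumericVector x, IntegerVector xdim,
                        NumericVector w, NumericVector bias) {
  int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  int Cout = bias.size();
  arma::mat W2(const_cast<double*>(w.begin()), 27 * Cin, Cout, false, true);
  NumericVector out((long)X * Y * Z * Cout);
  const long plane = (long)X * Y;
  const long ovol = plane * Z;
  for (int z = 0; z < Z; ++z) {
    arma::mat col = build_col(x.begin(), X, Y, Z, Cin, z);
    arma::mat ys = col * W2;                     // (X*Y) x Cout
    for (int co = 0; co < Cout; ++co) {
      double b = bias[co];
      const double* sp = ys.colptr(co);
      double* dp = out.begin() + (long)co * ovol + (long)z * plane;
      for (long i = 0; i < plane; ++i) dp[i] = sp[i] + b;
    }
  }
  out.attr("dim") = IntegerVector::create(X, Y, Z, Cout);
  return out;
}

// [[Rcpp::export]]
List conv3_bwd(NumericVector x, IntegerVector xdim, NumericVector w,
               NumericVector gy, int Cout) {
  int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  arma::mat W2(const_cast<double*>(w.begin()), 27 * Cin, Cout, false, true);
  NumericVector gx((long)X * Y * Z * Cin);
  arma::mat gW(27 * Cin, Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  const long plane = (long)X * Y;
  const long vol = plane * Z;
  for (int z = 0; z < Z; ++z) {
    arma::mat col = build_col(x.begin(), X, Y, Z, Cin, z);
    arma::mat gys(plane, Cout);
    for (int co = 0; co < Cout; ++co) {
      const double* sp = gy.begin() + (long)co * vol + (long)z * plane;
      std::copy(sp, sp + plane, gys.colptr(co));
      gb[co] += arma::accu(gys.col(co));
    }
    gW += col.t() * gys;
    arma::mat gcol = gys * W2.t();               // (X*Y) x 27*Cin
    // scatter-add gcol back into gx (transpose of build_col)
    for (int ci = 0; ci < Cin; ++ci) {
      for (int kz = 0; kz < 3; ++kz) {
        int zz = z + kz - 1;
        if (zz < 0 || zz >= Z) continue;
        for (int ky = 0; ky < 3; ++ky) {
          for (int kx = 0; kx < 3; ++kx) {
            int c = kx + 3 * (ky + 3 * (kz + 3 * ci));
            const double* sp = gcol.colptr(c);
            double* dst = gx.begin() + (long)ci * vol + (long)zz * plane;
            for (int y = 0; y < Y; ++y) {
              int yy = y + ky - 1;
              if (yy < 0 || yy >= Y) continue;
              int x0 = std::max(0, 1 - kx);
              int x1 = std::min(X, X + 1 - kx);
              double* dp = dst + (long)yy * X + (x0 + kx - 1);
              const double* s = sp + (long)y * X + x0;
              for (int x_ = x0; x_ < x1; ++x_) *dp++ += *s++;
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(X, Y, Z, Cin);
  NumericVector gwv(gW.begin(), gW.end());
  gwv.attr("dim") = IntegerVector::create(3, 3, 3, Cin, Cout);
  return List::create(Named("gx") = gx, Named("gw") = gwv,
                      Named("gb") = NumericVector(gb.begin(), gb.end()));
}

// [[Rcpp::export]]
List maxpool3_fwd(NumericVector x, IntegerVector xdim) {
  int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  if (X % 2 || Y % 2 || Z % 2) stop("maxpool3 requires even spatial dims");
  int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  long ovol = (long)Xo * Yo * Zo;
  NumericVector y(ovol * C);
  IntegerVector idx(ovol * C);
  const long plane = (long)X * Y, vol = plane * Z;
  for (int c = 0; c < C; ++c) {
    const double* xp = x.begin() + (long)c * vol;
    double* yp = y.begin() + (long)c * ovol;
    int* ip = idx.begin() + (long)c * ovol;
    for (int z = 0; z < Zo; ++z)
      for (int yy = 0; yy < Yo; ++yy)
        for (int xx = 0; xx < Xo; ++xx) {
          double best = -1e300; long bi = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                long li = (long)(2 * xx + dx) + (long)X * (2 * yy + dy) +
                          plane * (2 * z + dz);
                if (xp[li] > best) { best = xp[li]; bi = li; }
              }
          long oi = (long)xx + (long)Xo * yy + (long)Xo * Yo * z;
          yp[oi] = best;
          ip[oi] = (int)bi;   // index within the channel's spatial volume
        }
  }
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export]]
NumericVector maxpool3_bwd(IntegerVector idx, NumericVector gy,
                           IntegerVector xdim) {
  int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  long vol = (long)X * Y * Z;
  long ovol = vol / 8;
  NumericVector gx(vol * C);
  for (int c = 0; c < C; ++c) {
    double* gp = gx.begin() + (long)c * vol;
    const double* gyp = gy.begin() + (long)c * ovol;
    const int* ip = idx.begin() + (long)c * ovol;
    for (long i = 0; i < ovol; ++i) gp[ip[i]] += gyp[i];
  }
  gx.attr("dim") = xdim;
  return gx;
}

// [[Rcpp::export]]
NumericVector upsample3_fwd(NumericVector x, IntegerVector xdim) {
  int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  NumericVector y((long)Xo * Yo * Zo * C);
  const long vol = (long)X * Y * Z, ovol = (long)Xo * Yo * Zo;
  for (int c = 0; c < C; ++c) {
    const double* xp = x.begin() + (long)c * vol;
    double* yp = y.begin() + (long)c * ovol;
    for (int z = 0; z < Zo; ++z)
      for (int yy = 0; yy < Yo; ++yy) {
        const double* row = xp + (long)(z / 2) * X * Y + (long)(yy / 2) * X;
        double* orow = yp + (long)z * Xo * Yo + (long)yy * Xo;
        for (int xx = 0; xx < Xo; ++xx) orow[xx] = row[xx / 2];
      }
  }
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  return y;
}

// [[Rcpp::export]]
NumericVector upsample3_bwd(NumericVector gy, IntegerVector xdim) {
  // xdim: dims of the (smaller) upsample input
  int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  NumericVector gx((long)X * Y * Z * C);
  const long vol = (long)X * Y * Z, ovol = (long)Xo * Yo * Zo;
  for (int c = 0; c < C; ++c) {
    double* gp = gx.begin() + (long)c * vol;
    const double* gyp = gy.begin() + (long)c * ovol;
    for (int z = 0; z < Zo; ++z)
      for (int yy = 0; yy < Yo; ++yy) {
        double* row = gp + (long)(z / 2) * X * Y + (long)(yy / 2) * X;
        const double* orow = gyp + (long)z * Xo * Yo + (long)yy * Xo;
        for (int xx = 0; xx < Xo; ++xx) row[xx / 2] += orow[xx];
      }
  }
  gx.attr("dim") = xdim;
  return gx;
}
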