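// Low-level 3D network kernels: 3x3x3 convolution (im2col + GEMM),
// 2x2x2 average pooling and nearest-neighbour upsampling, with backward
// passes. Arrays are channel-LAST, dim = (Z, Y, X, C), column-major as
// stored by R, so each channel is a contiguous V = Z*Y*X block and the
// z-axis is the fastest: im2col columns can be filled with contiguous
// memcpy runs and the convolution is a single (V x 27C) * (27C x Cout)
// GEMM.
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& Z, int& Y, int& X,
                             int& C) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-D (Z, Y, X, C) array");
  Z = d[0]; Y = d[1]; X = d[2]; C = d[3];
}

// im2col for a 3x3x3 neighbourhood with zero padding; column j = o + 27*c
// where o = (dz+1) + 3*(dy+1) + 9*(dx+1).
static arma::mat im2col3(const double* x, int Z, int Y, int X, int C) {
  const arma::uword V = (arma::uword)Z * Y * X;
  arma::mat A(V, 27 * (arma::uword)C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (arma::uword)c * V;
    for (int dx = -1; dx <= 1; ++dx) {
      const int x0 = std::max(0, -dx), x1 = X - 1 - std::max(0, dx);
      for (int dy = -1; dy <= 1; ++dy) {
        const int y0 = std::max(0, -dy), y1 = Y - 1 - std::max(0, dy);
        for (int dz = -1; dz <= 1; ++dz) {
          const int z0 = std::max(0, -dz), z1 = Z - 1 - std::max(0, dz);
          const int o = (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1);
          const int L = z1 - z0 + 1;
          if (L <= 0) continue;
          double* Acol = A.colptr(o + 27 * (arma::uword)c);
          for (int xx = x0; xx <= x1; ++xx)
            for (int yy = y0; yy <= y1; ++yy) {
              const arma::uword v0 =
                  (arma::uword)z0 + (arma::uword)Z * (yy + (arma::uword)Y * xx);
              const arma::uword s0 =
                  (arma::uword)(z0 + dz) +
                  (arma::uword)Z * ((yy + dy) + (arma::uword)Y * (xx + dx));
              std::memcpy(Acol + v0, xc + s0, sizeof(double) * L);
            }
        }
      }
    }
  }
  return A;
}

// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector x, NumericMatrix W, NumericVector b) {
  int Z, Y, X, C;
  get_dims4(x, Z, Y, X, C);
  const int Cout = W.ncol();
  if (W.nrow() != 27 * C) stop("weight matrix must be (27*Cin) x Cout");
  arma::mat A = im2col3(x.begin(), Z, Y, X, C);
  arma::mat Wm(W.begin(), 27 * (arma::uword)C, Cout, false);
  arma::mat Ym = A * Wm;  // V x Cout
  arma::rowvec bv(b.begin(), Cout);
  Ym.each_row() += bv;
  NumericVector out(Ym.begin(), Ym.end());
  out.attr("dim") = IntegerVector::create(Z, Y, X, Cout);
  return out;
}

// [[Rcpp::export]]
List conv3d_bwd(NumericVector x, NumericMatrix W, NumericVector gy,
                bool need_gx = true) {
  int Z, Y, X, C;
  get_dims4(x, Z, Y, X, C);
  const int Cout = W.ncol();
  const arma::uword V = (arma::uword)Z * Y * X;
  arma::mat A = im2col3(x.begin(), Z, Y, X, C);
  arma::mat Gy((double*)gy.begin(), V, Cout, false);
  arma::mat Wm(W.begin(), 27 * (arma::uword)C, Cout, false);
  arma::mat gW = A.t() * Gy;                  // 27C x Cout
  arma::rowvec gb = arma::sum(Gy, 0);         // Cout
  NumericVector gx(need_gx ? x.size() : 1);
  if (need_gx) {
    arma::mat GA = Gy * Wm.t();               // V x 27C
    double* gxp = gx.begin();
    for (int c = 0; c < C; ++c) {
      double* gxc = gxp + (arma::uword)c * V;
      for (int dx = -1; dx <= 1; ++dx) {
        const int x0 = std::max(0, -dx), x1 = X - 1 - std::max(0, dx);
        for (int dy = -1; dy <= 1; ++dy) {
          const int y0 = std::max(0, -dy), y1 = Y - 1 - std::max(0, dy);
          for (int dz = -1; dz <= 1; ++dz) {
            const int z0 = std::max(0, -dz), z1 = Z - 1 - std::max(0, dz);
            const int o = (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1);
            const int L = z1 - z0 + 1;
            if (L <= 0) continue;
            const double* Gcol = GA.colptr(o + 27 * (arma::uword)c);
            for (int xx = x0; xx <= x1; ++xx)
              for (int yy = y0; yy <= y1; ++yy) {
                const arma::uword v0 =
                    (arma::uword)z0 +
                    (arma::uword)Z * (yy + (arma::uword)Y * xx);
                const arma::uword s0 =
                    (arma::uword)(z0 + dz) +
                    (arma::uword)Z * ((yy + dy) + (arma::uword)Y * (xx + dx));
                const double* src = Gcol + v0;
                double* dst = gxc + s0;
                for (int i = 0; i < L; ++i) dst[i] += src[i];
              }
          }
        }
      }
    }
    gx.attr("dim") = IntegerVector::create(Z, Y, X, C);
  }
  NumericMatrix gWr(27 * C, Cout);
  std::copy(gW.begin(), gW.end(), gWr.begin());
  return List::create(_["gx"] = gx, _["gW"] = gWr,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// [[Rcpp::export]]
NumericVector avgpool2_fwd(NumericVector x) {
  int Z, Y, X, C;
  get_dims4(x, Z, Y, X, C);
  if (Z % 2 || Y % 2 || X % 2) stop("spatial dims must be even for 2x pooling");
  const int Zo = Z / 2, Yo = Y / 2, Xo = X / 2;
  const R_xlen_t V = (R_xlen_t)Z * Y * X, Vo = (R_xlen_t)Zo * Yo * Xo;
  NumericVector out(Vo * C);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + c * V;
    double* oc = op + c * Vo;
    for (int xx = 0; xx < Xo; ++xx)
      for (int yy = 0; yy < Yo; ++yy)
        for (int zz = 0; zz < Zo; ++zz) {
          double s = 0;
          for (int jx = 0; jx < 2; ++jx)
            for (int jy = 0; jy < 2; ++jy) {
              const double* src =
                  xc + (R_xlen_t)(2 * zz) +
                  (R_xlen_t)Z * ((2 * yy + jy) + (R_xlen_t)Y * (2 * xx + jx));
              s += src[0] + src[1];
            }
          oc[zz + (R_xlen_t)Zo * (yy + (R_xlen_t)Yo * xx)] = s / 8.0;
        }
  }
  out.attr("dim") = IntegerVector::create(Zo, Yo, Xo, C);
  return out;
}

// [[Rcpp::export]]
NumericVector avgpool2_bwd(NumericVector gy) {
  int Zo, Yo, Xo, C;
  get_dims4(gy, Zo, Yo, Xo, C);
  const int Z = 2 * Zo, Y = 2 * Yo, X = 2 * Xo;
  const R_xlen_t V = (R_xlen_t)Z * Y * X, Vo = (R_xlen_t)Zo * Yo * Xo;
  NumericVector gx(V * C);
  const double* gp = gy.begin();
  double* op = gx.begin();
  for (int c = 0; c < C; ++c) {
    const double* gc = gp + c * Vo;
    double* oc = op + c * V;
    for (int xx = 0; xx < Xo; ++xx)
      for (int yy = 0; yy < Yo; ++yy)
        for (int zz = 0; zz < Zo; ++zz) {
          const double g =
              gc[zz + (R_xlen_t)Zo * (yy + (R_xlen_t)Yo * xx)] / 8.0;
          for (int jx = 0; jx < 2; ++jx)
            for (int jy = 0; jy < 2; ++jy) {
              double* dst =
                  oc + (R_xlen_t)(2 * zz) +
                  (R_xlen_t)Z * ((2 * yy + jy) + (R_xlen_t)Y * (2 * xx + jx));
              dst[0] += g;
              dst[1] += g;
            }
        }
  }
  gx.attr("dim") = IntegerVector::create(Z, Y, X, C);
  return gx;
}

// [[Rcpp::export]]
NumericVector upsample2_fwd(NumericVector x) {
  int Z, Y, X, C;
  get_dims4(x, Z, Y, X, C);
  const int Zo = 2 * Z, Yo = 2 * Y, Xo = 2 * X;
  const R_xlen_t V = (R_xlen_t)Z * Y * X, Vo = (R_xlen_t)Zo * Yo * Xo;
  NumericVector out(Vo * C);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + c * V;
    double* oc = op + c * Vo;
    for (int xx = 0; xx < Xo; ++xx)
      for (int yy = 0; yy < Yo; ++yy) {
        const double* src =
            xc + (R_xlen_t)Z * ((yy / 2) + (R_xlen_t)Y * (xx / 2));
        double* dst = oc + (R_xlen_t)Zo * (yy + (R_xlen_t)Yo * xx);
        for (int zz = 0; zz < Z; ++zz) {
          dst[2 * zz] = src[zz];
          dst[2 * zz + 1] = src[zz];
        }
      }
  }
  out.attr("dim") = IntegerVector::create(Zo, Yo, Xo, C);
  return out;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd(NumericVector gy) {
  int Zo, Yo, Xo, C;
  get_dims4(gy, Zo, Yo, Xo, C);
  const int Z = Zo / 2, Y = Yo / 2, X = Xo / 2;
  const R_xlen_t V = (R_xlen_t)Z * Y * X, Vo = (R_xlen_t)Zo * Yo * Xo;
  NumericVector gx(V * C);
  const double* gp = gy.begin();
  double* op = gx.begin();
  for (int c = 0; c < C; ++c) {
    const double* gc = gp + c * Vo;
    double* oc = op + c * V;
    for (int xx = 0; xx < Xo; ++xx)
      for (int yy = 0; yy < Yo; ++yy) {
        const double* src = gc + (R_xlen_t)Zo * (yy + (R_xlen_t)Yo * xx);
        double* dst = oc + (R_xlen_t)Z * ((yy / 2) + (R_xlen_t)Y * (xx / 2));
        for (int zz = 0; zz < Z; ++zz)
          dst[zz] += src[2 * zz] + src[2 * zz + 1];
      }
  }
  gx.attr("dim") = IntegerVector::create(Z, Y, X, C);
  return gx;
}
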