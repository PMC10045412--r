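// 2-D cross-correlation kernels for the network core.
// Tensor layout everywhere: x (H, W, C, N), weights (kh, kw, C/groups, O),
// outputs (Ho, Wo, O, N); all column-major R arrays, zero padding.
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Fill the im2col matrix M (Ho*Wo x kh*kw*Cpg) for sample n, group gi.
static void im2col(const double* xp, arma::mat& M,
                   int H, int W, int C, int n,
                   int kh, int kw, int Cpg, int gi,
                   int Ho, int Wo, int stride, int pad) {
  for (int ci = 0; ci < Cpg; ++ci) {
    const int c = gi * Cpg + ci;
    const double* xc = xp + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ci * kh * kw + kj * kh + ki;
        double* Mcol = M.colptr(col);
        // valid output-row range: 0 <= i*stride - pad + ki < H
        int i0 = 0;
        while (i0 < Ho && i0 * stride - pad + ki < 0) ++i0;
        int i1 = Ho;
        while (i1 > i0 && (i1 - 1) * stride - pad + ki >= H) --i1;
        for (int j = 0; j < Wo; ++j) {
          const int jj = j * stride - pad + kj;
          double* Mj = Mcol + (R_xlen_t)Ho * j;
          if (jj < 0 || jj >= W) {
            std::fill(Mj, Mj + Ho, 0.0);
          } else {
            const double* xcol = xc + (R_xlen_t)H * jj;
            if (i0 > 0) std::fill(Mj, Mj + i0, 0.0);
            if (stride == 1) {
              std::copy(xcol + i0 - pad + ki, xcol + i1 - pad + ki, Mj + i0);
            } else {
              for (int i = i0; i < i1; ++i) Mj[i] = xcol[i * stride - pad + ki];
            }
            if (i1 < Ho) std::fill(Mj + i1, Mj + Ho, 0.0);
          }
        }
      }
    }
  }
}

// Scatter-add of the im2col gradient back onto dx (col2im).
static void col2im_add(double* dxp, const arma::mat& dM,
                       int H, int W, int C, int n,
                       int kh, int kw, int Cpg, int gi,
                       int Ho, int Wo, int stride, int pad) {
  for (int ci = 0; ci < Cpg; ++ci) {
    const int c = gi * Cpg + ci;
    double* xc = dxp + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ci * kh * kw + kj * kh + ki;
        const double* Mcol = dM.colptr(col);
        int i0 = 0;
        while (i0 < Ho && i0 * stride - pad + ki < 0) ++i0;
        int i1 = Ho;
        while (i1 > i0 && (i1 - 1) * stride - pad + ki >= H) --i1;
        for (int j = 0; j < Wo; ++j) {
          const int jj = j * stride - pad + kj;
          if (jj < 0 || jj >= W) continue;
          double* xcol = xc + (R_xlen_t)H * jj;
          const double* Mj = Mcol + (R_xlen_t)Ho * j;
          if (stride == 1) {
            double* xd = xcol - pad + ki;
            for (int i = i0; i < i1; ++i) xd[i] += Mj[i];
          } else {
            for (int i = i0; i < i1; ++i) xcol[i * stride - pad + ki] += Mj[i];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericVector w,
                        int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cpg = wd[2], O = wd[3];
  if (C != Cpg * groups) stop("channel count does not match weights/groups");
  if (O % groups != 0) stop("output channels not divisible by groups");
  const int Opg = O / groups;
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("input smaller than kernel");

  NumericVector y((R_xlen_t)Ho * Wo * O * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, O, N);
  arma::mat M(Ho * Wo, kh * kw * Cpg);
  const double* xp = x.begin();
  double* yp = y.begin();

  for (int n = 0; n < N; ++n) {
    for (int gi = 0; gi < groups; ++gi) {
      im2col(xp, M, H, W, C, n, kh, kw, Cpg, gi, Ho, Wo, stride, pad);
      const arma::mat Wg(const_cast<double*>(w.begin()) +
                             (R_xlen_t)kh * kw * Cpg * gi * Opg,
                         kh * kw * Cpg, Opg, false, true);
      arma::mat Yg(yp + (R_xlen_t)Ho * Wo * (gi * Opg + (R_xlen_t)O * n),
                   Ho * Wo, Opg, false, true);
      Yg = M * Wg;
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
               int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cpg = wd[2], O = wd[3];
  const int Opg = O / groups;
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);

  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw((R_xlen_t)kh * kw * Cpg * O);
  dw.attr("dim") = IntegerVector::create(kh, kw, Cpg, O);

  arma::mat M(Ho * Wo, kh * kw * Cpg);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();

  for (int n = 0; n < N; ++n) {
    for (int gi = 0; gi < groups; ++gi) {
      im2col(xp, M, H, W, C, n, kh, kw, Cpg, gi, Ho, Wo, stride, pad);
      const arma::mat Wg(const_cast<double*>(w.begin()) +
                             (R_xlen_t)kh * kw * Cpg * gi * Opg,
                         kh * kw * Cpg, Opg, false, true);
      const arma::mat dYg(const_cast<double*>(dyp) +
                              (R_xlen_t)Ho * Wo * (gi * Opg + (R_xlen_t)O * n),
                          Ho * Wo, Opg, false, true);
      arma::mat dWg(dw.begin() + (R_xlen_t)kh * kw * Cpg * gi * Opg,
                    kh * kw * Cpg, Opg, false, true);
      dWg += M.t() * dYg;
      arma::mat dM = dYg * Wg.t();
      col2im_add(dxp, dM, H, W, C, n, kh, kw, Cpg, gi, Ho, Wo, stride, pad);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}
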