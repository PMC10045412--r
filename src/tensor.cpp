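// Support kernels for the network core: per-(channel,sample) affine maps
// (the workhorse of switchable normalization once its statistics are pooled
// into C x N tables), fused column sums, and channel concat/split for the
// (H, W, C, N) tensor layout.
#include <Rcpp.h>
using namespace Rcpp;

// y = x * S[c,n] + T[c,n]
// [[Rcpp::export]]
NumericVector cn_affine(NumericVector x, NumericMatrix S, NumericMatrix T) {
  IntegerVector d = x.attr("dim");
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  NumericVector y(x.size());
  y.attr("dim") = d;
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double s = S(c, n), t = T(c, n);
      const R_xlen_t off = (R_xlen_t)HW * (c + (R_xlen_t)C * n);
      for (int i = 0; i < HW; ++i) yp[off + i] = xp[off + i] * s + t;
    }
  return y;
}

// z = a * S[c,n] + b * U[c,n] + T[c,n]
// [[Rcpp::export]]
NumericVector cn_affine2(NumericVector a, NumericMatrix S, NumericVector b,
                         NumericMatrix U, NumericMatrix T) {
  IntegerVector d = a.attr("dim");
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  NumericVector z(a.size());
  z.attr("dim") = d;
  const double* ap = a.begin();
  const double* bp = b.begin();
  double* zp = z.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double s = S(c, n), u = U(c, n), t = T(c, n);
      const R_xlen_t off = (R_xlen_t)HW * (c + (R_xlen_t)C * n);
      for (int i = 0; i < HW; ++i)
        zp[off + i] = ap[off + i] * s + bp[off + i] * u + t;
    }
  return z;
}

// per-(c,n) sums of x and x^2 in one pass; rows = C, cols = N (stacked)
// [[Rcpp::export]]
List cn_sums_sq(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  NumericMatrix s1(C, N), s2(C, N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = (R_xlen_t)HW * (c + (R_xlen_t)C * n);
      double a = 0, b = 0;
      for (int i = 0; i < HW; ++i) {
        const double v = xp[off + i];
        a += v;
        b += v * v;
      }
      s1(c, n) = a;
      s2(c, n) = b;
    }
  return List::create(_["s1"] = s1, _["s2"] = s2);
}

// per-(c,n) sums of a and a*b in one pass
// [[Rcpp::export]]
List cn_sums_prod(NumericVector a, NumericVector b) {
  IntegerVector d = a.attr("dim");
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  NumericMatrix s1(C, N), s2(C, N);
  const double* ap = a.begin();
  const double* bp = b.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = (R_xlen_t)HW * (c + (R_xlen_t)C * n);
      double u = 0, v = 0;
      for (int i = 0; i < HW; ++i) {
        u += ap[off + i];
        v += ap[off + i] * bp[off + i];
      }
      s1(c, n) = u;
      s2(c, n) = v;
    }
  return List::create(_["sa"] = s1, _["sab"] = s2);
}

// concatenate along the channel dimension
// [[Rcpp::export]]
NumericVector cat_ch(List xs) {
  const int K = xs.size();
  std::vector<NumericVector> v(K);
  int Ctot = 0;
  IntegerVector d0;
  for (int k = 0; k < K; ++k) {
    v[k] = as<NumericVector>(xs[k]);
    IntegerVector d = v[k].attr("dim");
    if (k == 0) d0 = d;
    Ctot += d[2];
  }
  const int HW = d0[0] * d0[1], N = d0[3];
  NumericVector y((R_xlen_t)HW * Ctot * N);
  y.attr("dim") = IntegerVector::create(d0[0], d0[1], Ctot, N);
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    R_xlen_t ofs = (R_xlen_t)HW * Ctot * n;
    for (int k = 0; k < K; ++k) {
      IntegerVector d = v[k].attr("dim");
      const R_xlen_t len = (R_xlen_t)HW * d[2];
      std::copy(v[k].begin() + (R_xlen_t)HW * d[2] * n,
                v[k].begin() + (R_xlen_t)HW * d[2] * (n + 1), yp + ofs);
      ofs += len;
    }
  }
  return y;
}

// split along the channel dimension into blocks of the given sizes
// [[Rcpp::export]]
List split_ch(NumericVector x, IntegerVector sizes) {
  IntegerVector d = x.attr("dim");
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  const int K = sizes.size();
  List out(K);
  const double* xp = x.begin();
  std::vector<double*> ptrs(K);
  for (int k = 0; k < K; ++k) {
    NumericVector y((R_xlen_t)HW * sizes[k] * N);
    y.attr("dim") = IntegerVector::create(d[0], d[1], sizes[k], N);
    out[k] = y;
    ptrs[k] = as<NumericVector>(out[k]).begin();
  }
  for (int n = 0; n < N; ++n) {
    R_xlen_t ofs = (R_xlen_t)HW * C * n;
    for (int k = 0; k < K; ++k) {
      const R_xlen_t len = (R_xlen_t)HW * sizes[k];
      std::copy(xp + ofs, xp + ofs + len, ptrs[k] + (R_xlen_t)HW * sizes[k] * n);
      ofs += len;
    }
  }
  return out;
}
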