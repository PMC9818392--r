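// im2col + GEMM 2-D convolution kernels (forward and backward).
//
// Tensor layout follows R's column-major arrays:
//   feature maps  x : (h, w, c_in, n)
//   kernels       w : (kh, kw, c_in, c_out), kh == kw, odd or 1
//   output        y : (oh, ow, c_out, n)
// "Same" zero padding of k/2 is always applied, so oh = ceil(h / stride).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_dim(int h, int k, int pad, int stride) {
  return (h + 2 * pad - k) / stride + 1;
}

// gather x into the im2col matrix M: rows index (oi, oj, sample),
// columns index (ki, kj, c_in); padding contributes zeros.
static arma::mat im2col(const double* x, int h, int w, int ci, int n,
                        int k, int pad, int stride, int oh, int ow) {
  arma::mat M(static_cast<arma::uword>(oh) * ow * n,
              static_cast<arma::uword>(k) * k * ci, arma::fill::zeros);
  for (int s = 0; s < n; ++s) {
    for (int c = 0; c < ci; ++c) {
      const double* xs = x + (static_cast<size_t>(s) * ci + c) * h * w;
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const arma::uword col = ki + k * (kj + k * c);
          for (int oj = 0; oj < ow; ++oj) {
            const int j = oj * stride - pad + kj;
            if (j < 0 || j >= w) continue;
            for (int oi = 0; oi < oh; ++oi) {
              const int i = oi * stride - pad + ki;
              if (i < 0 || i >= h) continue;
              M(oi + static_cast<arma::uword>(oh) * (oj + static_cast<arma::uword>(ow) * s),
                col) = xs[i + static_cast<size_t>(h) * j];
            }
          }
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
NumericVector conv2d_fw_cpp(NumericVector x, NumericVector wt,
                            NumericVector b, int stride) {
  IntegerVector xd = x.attr("dim"), wd = wt.attr("dim");
  const int h = xd[0], w = xd[1], ci = xd[2], n = xd[3];
  const int k = wd[0], co = wd[3];
  if (wd[1] != k) stop("conv2d: kernels must be square");
  if (wd[2] != ci) stop("conv2d: input has %d channels but kernel expects %d", ci, wd[2]);
  const int pad = k / 2;
  const int oh = out_dim(h, k, pad, stride), ow = out_dim(w, k, pad, stride);

  arma::mat M = im2col(x.begin(), h, w, ci, n, k, pad, stride, oh, ow);
  arma::mat W(wt.begin(), static_cast<arma::uword>(k) * k * ci, co, false);
  arma::mat Y = M * W;  // (oh*ow*n) x co

  NumericVector out(static_cast<R_xlen_t>(oh) * ow * co * n);
  out.attr("dim") = IntegerVector::create(oh, ow, co, n);
  double* o = out.begin();
  for (int s = 0; s < n; ++s)
    for (int c = 0; c < co; ++c) {
      const double bias = b[c];
      double* os = o + (static_cast<size_t>(s) * co + c) * oh * ow;
      const arma::uword r0 = static_cast<arma::uword>(s) * oh * ow;
      for (int q = 0; q < oh * ow; ++q) os[q] = Y(r0 + q, c) + bias;
    }
  return out;
}

// [[Rcpp::export]]
List conv2d_bw_cpp(NumericVector x, NumericVector wt, NumericVector dy,
                   int stride) {
  IntegerVector xd = x.attr("dim"), wd = wt.attr("dim"), yd = dy.attr("dim");
  const int h = xd[0], w = xd[1], ci = xd[2], n = xd[3];
  const int k = wd[0], co = wd[3];
  const int oh = yd[0], ow = yd[1];
  const int pad = k / 2;

  // gradient wrt output as a (oh*ow*n) x co matrix, rows ordered (oi, oj, s)
  arma::mat G(static_cast<arma::uword>(oh) * ow * n, co);
  const double* dyp = dy.begin();
  for (int s = 0; s < n; ++s)
    for (int c = 0; c < co; ++c) {
      const double* ds = dyp + (static_cast<size_t>(s) * co + c) * oh * ow;
      const arma::uword r0 = static_cast<arma::uword>(s) * oh * ow;
      for (int q = 0; q < oh * ow; ++q) G(r0 + q, c) = ds[q];
    }

  arma::mat M = im2col(x.begin(), h, w, ci, n, k, pad, stride, oh, ow);
  arma::mat W(wt.begin(), static_cast<arma::uword>(k) * k * ci, co, false);

  arma::rowvec dbv = arma::sum(G, 0);
  arma::mat dW = M.t() * G;          // (k*k*ci) x co
  arma::mat dXc = G * W.t();         // (oh*ow*n) x (k*k*ci)

  NumericVector dx(static_cast<R_xlen_t>(h) * w * ci * n);
  dx.attr("dim") = IntegerVector::create(h, w, ci, n);
  double* dxp = dx.begin();
  for (int s = 0; s < n; ++s) {
    for (int c = 0; c < ci; ++c) {
      double* xs = dxp + (static_cast<size_t>(s) * ci + c) * h * w;
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const arma::uword col = ki + k * (kj + k * c);
          for (int oj = 0; oj < ow; ++oj) {
            const int j = oj * stride - pad + kj;
            if (j < 0 || j >= w) continue;
            for (int oi = 0; oi < oh; ++oi) {
              const int i = oi * stride - pad + ki;
              if (i < 0 || i >= h) continue;
              xs[i + static_cast<size_t>(h) * j] +=
                dXc(oi + static_cast<arma::uword>(oh) *
                          (oj + static_cast<arma::uword>(ow) * s), col);
            }
          }
        }
      }
    }
  }

  NumericVector dwv(wt.size());
  dwv.attr("dim") = wt.attr("dim");
  std::copy(dW.begin(), dW.end(), dwv.begin());
  NumericVector db(co);
  std::copy(dbv.begin(), dbv.end(), db.begin());
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = db);
}
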