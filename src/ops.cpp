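// Low-level numerical kernels for the network and the retinex surround.
// Tensors are R arrays in column-major (H, W, C, N) layout; weights are
// (k, k, Cin, Cout). All convolutions are stride 1 with "same" zero padding;
// the transposed convolution is the fixed 2x2 stride-2 upsampling kernel.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// reflect-101 index fold (mirror without repeating the border pixel)
static inline int refl(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

static void im2col(const double* xs, int H, int W, int Cin, int k, int dilation,
                   int pad, arma::mat& M) {
  const int npix = H * W;
  M.zeros();
  for (int c = 0; c < Cin; ++c)
    for (int b = 0; b < k; ++b)
      for (int a = 0; a < k; ++a) {
        const int q = a + k * (b + k * c);
        for (int j = 0; j < W; ++j) {
          const int jj = j + b * dilation - pad;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int ii = i + a * dilation - pad;
            if (ii < 0 || ii >= H) continue;
            M(i + H * j, q) = xs[ii + H * jj + npix * c];
          }
        }
      }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int dilation) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int pad = dilation * (k - 1) / 2;
  const int npix = H * W, K = k * k * Cin;
  arma::mat Wmat(w.begin(), K, Cout, false);
  arma::rowvec bias(b.begin(), Cout);
  NumericVector out((R_xlen_t)npix * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat M(npix, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (R_xlen_t)n * npix * Cin, H, W, Cin, k, dilation, pad, M);
    arma::mat O = M * Wmat;
    O.each_row() += bias;
    std::copy(O.begin(), O.end(), out.begin() + (R_xlen_t)n * npix * Cout);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int dilation) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int pad = dilation * (k - 1) / 2;
  const int npix = H * W, K = k * k * Cin;
  arma::mat Wmat(w.begin(), K, Cout, false);
  NumericVector gx((R_xlen_t)npix * Cin * N);
  gx.attr("dim") = xd;
  NumericVector gw((R_xlen_t)K * Cout);
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  arma::mat GW(gw.begin(), K, Cout, false, true);
  arma::mat M(npix, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (R_xlen_t)n * npix * Cin, H, W, Cin, k, dilation, pad, M);
    arma::mat GY(gy.begin() + (R_xlen_t)n * npix * Cout, npix, Cout, false);
    GW += M.t() * GY;
    for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(GY.col(co));
    arma::mat GC = GY * Wmat.t();  // npix x K
    double* gxs = gx.begin() + (R_xlen_t)n * npix * Cin;
    for (int c = 0; c < Cin; ++c)
      for (int b2 = 0; b2 < k; ++b2)
        for (int a = 0; a < k; ++a) {
          const int q = a + k * (b2 + k * c);
          for (int j = 0; j < W; ++j) {
            const int jj = j + b2 * dilation - pad;
            if (jj < 0 || jj >= W) continue;
            for (int i = 0; i < H; ++i) {
              const int ii = i + a * dilation - pad;
              if (ii < 0 || ii >= H) continue;
              gxs[ii + H * jj + npix * c] += GC(i + H * j, q);
            }
          }
        }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector cpp_convt2_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int Cout = wd[3];
  const int H2 = 2 * H, W2 = 2 * W;
  const R_xlen_t npix = (R_xlen_t)H * W, opix = (R_xlen_t)H2 * W2;
  NumericVector out(opix * Cout * N);
  out.attr("dim") = IntegerVector::create(H2, W2, Cout, N);
  // w index (a, b, ci, co) -> a + 2*(b + 2*(ci + Cin*co))
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (R_xlen_t)n * npix * Cin;
    double* os = out.begin() + (R_xlen_t)n * opix * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double bias = b[co];
      for (R_xlen_t p = 0; p < opix; ++p) os[p + opix * co] = bias;
      for (int ci = 0; ci < Cin; ++ci) {
        const double* wk = w.begin() + 4 * (ci + (R_xlen_t)Cin * co);
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            const double v = xs[i + H * j + npix * ci];
            if (v == 0.0) continue;
            double* o0 = os + opix * co + (2 * i) + (R_xlen_t)H2 * (2 * j);
            o0[0] += v * wk[0];          // a=0,b=0
            o0[1] += v * wk[1];          // a=1,b=0
            o0[H2] += v * wk[2];         // a=0,b=1
            o0[H2 + 1] += v * wk[3];     // a=1,b=1
          }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_convt2_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int Cout = wd[3];
  const int H2 = 2 * H, W2 = 2 * W;
  const R_xlen_t npix = (R_xlen_t)H * W, opix = (R_xlen_t)H2 * W2;
  NumericVector gx(npix * Cin * N);
  gx.attr("dim") = xd;
  NumericVector gw(4 * (R_xlen_t)Cin * Cout);
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (R_xlen_t)n * npix * Cin;
    const double* gs = gy.begin() + (R_xlen_t)n * opix * Cout;
    double* gxs = gx.begin() + (R_xlen_t)n * npix * Cin;
    for (int co = 0; co < Cout; ++co) {
      const double* g0 = gs + opix * co;
      for (R_xlen_t p = 0; p < opix; ++p) gb[co] += g0[p];
      for (int ci = 0; ci < Cin; ++ci) {
        const double* wk = w.begin() + 4 * (ci + (R_xlen_t)Cin * co);
        double* gwk = gw.begin() + 4 * (ci + (R_xlen_t)Cin * co);
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            const double v = xs[i + H * j + npix * ci];
            const double* gq = g0 + (2 * i) + (R_xlen_t)H2 * (2 * j);
            const double g00 = gq[0], g10 = gq[1], g01 = gq[H2], g11 = gq[H2 + 1];
            gxs[i + H * j + npix * ci] +=
                g00 * wk[0] + g10 * wk[1] + g01 * wk[2] + g11 * wk[3];
            gwk[0] += v * g00;
            gwk[1] += v * g10;
            gwk[2] += v * g01;
            gwk[3] += v * g11;
          }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  const R_xlen_t npix = (R_xlen_t)H * W, opix = (R_xlen_t)Ho * Wo;
  NumericVector out(opix * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(opix * C * N);  // 0-based linear index into x
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = npix * (c + (R_xlen_t)C * n);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          R_xlen_t p00 = base + (2 * i) + (R_xlen_t)H * (2 * j);
          R_xlen_t best = p00;
          double bv = x[p00];
          if (x[p00 + 1] > bv) { bv = x[p00 + 1]; best = p00 + 1; }
          if (x[p00 + H] > bv) { bv = x[p00 + H]; best = p00 + H; }
          if (x[p00 + H + 1] > bv) { bv = x[p00 + H + 1]; best = p00 + H + 1; }
          out[o + i + (R_xlen_t)Ho * j] = bv;
          idx[o + i + (R_xlen_t)Ho * j] = (int)best;
        }
      o += opix;
    }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector gy, IntegerVector idx,
                               IntegerVector xdim) {
  R_xlen_t nx = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(nx);
  gx.attr("dim") = xdim;
  for (R_xlen_t p = 0; p < gy.size(); ++p) gx[idx[p]] += gy[p];
  return gx;
}

// Separable convolution with a symmetric 1-D kernel and reflect-101 borders.
// [[Rcpp::export]]
NumericMatrix cpp_sepconv_reflect(NumericMatrix img, NumericVector kernel) {
  const int H = img.nrow(), W = img.ncol();
  const int h = ((int)kernel.size() - 1) / 2;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int t = -h; t <= h; ++t) s += kernel[t + h] * img(refl(i + t, H), j);
      tmp(i, j) = s;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int t = -h; t <= h; ++t) s += kernel[t + h] * tmp(i, refl(j + t, W));
      out(i, j) = s;
    }
  return out;
}
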