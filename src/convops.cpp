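// Compiled kernels for 2D convolution, pooling and bilinear resampling.
// Feature maps are dense arrays laid out [H, W, C] (column-major, H fastest),
// convolution weights [k, k, Cin/groups, Cout].
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad, int dil) {
  return (n + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// Unfold x [H,W,C] into [Ho*Wo, k*k*C]; column order (kh, kw, c), kh fastest.
static arma::mat im2col(const double* x, int H, int W, int C,
                        int k, int stride, int pad, int dil,
                        int Ho, int Wo) {
  arma::mat col(Ho * Wo, (arma::uword)k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* plane = x + (size_t)c * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        arma::uword cc = (arma::uword)c * k * k + kw * k + kh;
        double* dst = col.colptr(cc);
        for (int ow = 0; ow < Wo; ++ow) {
          int iw = ow * stride - pad + kw * dil;
          if (iw < 0 || iw >= W) continue;
          const double* src = plane + (size_t)iw * H;
          double* d = dst + (size_t)ow * Ho;
          for (int oh = 0; oh < Ho; ++oh) {
            int ih = oh * stride - pad + kh * dil;
            if (ih >= 0 && ih < H) d[oh] = src[ih];
          }
        }
      }
    }
  }
  return col;
}

// Fold gradient columns back onto the input grid (transpose of im2col).
static void col2im(const arma::mat& col, double* gx, int H, int W, int C,
                   int k, int stride, int pad, int dil, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* plane = gx + (size_t)c * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        arma::uword cc = (arma::uword)c * k * k + kw * k + kh;
        const double* src = col.colptr(cc);
        for (int ow = 0; ow < Wo; ++ow) {
          int iw = ow * stride - pad + kw * dil;
          if (iw < 0 || iw >= W) continue;
          double* d = plane + (size_t)iw * H;
          const double* s = src + (size_t)ow * Ho;
          for (int oh = 0; oh < Ho; ++oh) {
            int ih = oh * stride - pad + kh * dil;
            if (ih >= 0 && ih < H) d[ih] += s[oh];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w,
                         Nullable<NumericVector> bias,
                         int stride, int pad, int dil, int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2];
  int k = wd[0], cing = wd[2], cout = wd[3];
  if (C != cing * groups) stop("conv2d: input has %d channels but weights expect %d", C, cing * groups);
  int Ho = out_size(H, k, stride, pad, dil), Wo = out_size(W, k, stride, pad, dil);
  if (Ho < 1 || Wo < 1) stop("conv2d: input %dx%d too small for kernel %d (dilation %d)", H, W, k, dil);
  int coutg = cout / groups;
  arma::uword kk = (arma::uword)k * k * cing;
  NumericVector y((R_xlen_t)Ho * Wo * cout);
  arma::mat Y(y.begin(), (arma::uword)Ho * Wo, cout, false, true);
  arma::mat Wm(w.begin(), kk, cout, false, true);
  if (groups == 1) {
    arma::mat col = im2col(x.begin(), H, W, C, k, stride, pad, dil, Ho, Wo);
    Y = col * Wm;
  } else {
    for (int g = 0; g < groups; ++g) {
      arma::mat col = im2col(x.begin() + (size_t)g * cing * H * W, H, W, cing,
                             k, stride, pad, dil, Ho, Wo);
      Y.cols((arma::uword)g * coutg, (arma::uword)(g + 1) * coutg - 1) =
        col * Wm.cols((arma::uword)g * coutg, (arma::uword)(g + 1) * coutg - 1);
    }
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int c = 0; c < cout; ++c) {
      double bc = b[c];
      double* col = y.begin() + (size_t)c * Ho * Wo;
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) col[i] += bc;
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, cout);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad, int dil, int groups,
                    bool need_gx, bool need_gw) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = gy.attr("dim");
  int H = xd[0], W = xd[1];
  int k = wd[0], cing = wd[2], cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  int coutg = cout / groups;
  arma::uword kk = (arma::uword)k * k * cing;
  arma::mat GY(gy.begin(), (arma::uword)Ho * Wo, cout, false, true);
  arma::mat Wm(w.begin(), kk, cout, false, true);

  NumericVector gx, gw, gb(cout);
  if (need_gx) { gx = NumericVector((R_xlen_t)H * W * xd[2]); gx.attr("dim") = xd; }
  if (need_gw) { gw = NumericVector(w.length()); gw.attr("dim") = wd; }
  arma::mat GW;
  if (need_gw) GW = arma::mat(gw.begin(), kk, cout, false, true);

  for (int g = 0; g < groups; ++g) {
    arma::mat col = im2col(x.begin() + (size_t)g * cing * H * W, H, W, cing,
                           k, stride, pad, dil, Ho, Wo);
    arma::mat gyg = GY.cols((arma::uword)g * coutg, (arma::uword)(g + 1) * coutg - 1);
    if (need_gw)
      GW.cols((arma::uword)g * coutg, (arma::uword)(g + 1) * coutg - 1) = col.t() * gyg;
    if (need_gx) {
      arma::mat gcol = gyg * Wm.cols((arma::uword)g * coutg, (arma::uword)(g + 1) * coutg - 1).t();
      col2im(gcol, gx.begin() + (size_t)g * cing * H * W, H, W, cing,
             k, stride, pad, dil, Ho, Wo);
    }
  }
  for (int c = 0; c < cout; ++c) {
    double s = 0;
    const double* colp = gy.begin() + (size_t)c * Ho * Wo;
    for (size_t i = 0; i < (size_t)Ho * Wo; ++i) s += colp[i];
    gb[c] = s;
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 3x3 max pooling, stride 2, pad 1. Returns pooled map and argmax indices
// (1-based linear index into each [H,W] plane) for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2];
  int Ho = out_size(H, 3, 2, 1, 1), Wo = out_size(W, 3, 2, 1, 1);
  NumericVector y((R_xlen_t)Ho * Wo * C);
  IntegerVector idx((R_xlen_t)Ho * Wo * C);
  for (int c = 0; c < C; ++c) {
    const double* plane = x.begin() + (size_t)c * H * W;
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        double best = R_NegInf; int bi = 0;
        for (int kw = 0; kw < 3; ++kw) {
          int iw = ow * 2 - 1 + kw;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < 3; ++kh) {
            int ih = oh * 2 - 1 + kh;
            if (ih < 0 || ih >= H) continue;
            double v = plane[(size_t)iw * H + ih];
            if (v > best) { best = v; bi = iw * H + ih; }
          }
        }
        size_t o = (size_t)c * Ho * Wo + (size_t)ow * Ho + oh;
        y[o] = best; idx[o] = bi + 1;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gy, IntegerVector idx, int H, int W) {
  IntegerVector yd = gy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2];
  NumericVector gx((R_xlen_t)H * W * C);
  for (int c = 0; c < C; ++c) {
    double* plane = gx.begin() + (size_t)c * H * W;
    const double* gp = gy.begin() + (size_t)c * Ho * Wo;
    const int* ip = idx.begin() + (size_t)c * Ho * Wo;
    for (size_t i = 0; i < (size_t)Ho * Wo; ++i) plane[ip[i] - 1] += gp[i];
  }
  gx.attr("dim") = IntegerVector::create(H, W, C);
  return gx;
}

static void lin_coords(int n_in, int n_out, std::vector<int>& i0,
                       std::vector<int>& i1, std::vector<double>& wt) {
  i0.resize(n_out); i1.resize(n_out); wt.resize(n_out);
  double scale = (double)n_in / n_out;
  for (int i = 0; i < n_out; ++i) {
    double src = (i + 0.5) * scale - 0.5;
    if (src < 0) src = 0;
    if (src > n_in - 1) src = n_in - 1;
    int lo = (int)std::floor(src);
    int hi = std::min(lo + 1, n_in - 1);
    i0[i] = lo; i1[i] = hi; wt[i] = src - lo;
  }
}

// [[Rcpp::export]]
NumericVector cpp_bilinear(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2];
  std::vector<int> r0, r1, c0, c1; std::vector<double> rw, cw;
  lin_coords(H, Ho, r0, r1, rw);
  lin_coords(W, Wo, c0, c1, cw);
  NumericVector y((R_xlen_t)Ho * Wo * C);
  for (int c = 0; c < C; ++c) {
    const double* p = x.begin() + (size_t)c * H * W;
    double* q = y.begin() + (size_t)c * Ho * Wo;
    for (int ow = 0; ow < Wo; ++ow) {
      const double* pl = p + (size_t)c0[ow] * H;
      const double* pr = p + (size_t)c1[ow] * H;
      double wc = cw[ow];
      for (int oh = 0; oh < Ho; ++oh) {
        double wr = rw[oh];
        double top = pl[r0[oh]] * (1 - wc) + pr[r0[oh]] * wc;
        double bot = pl[r1[oh]] * (1 - wc) + pr[r1[oh]] * wc;
        q[(size_t)ow * Ho + oh] = top * (1 - wr) + bot * wr;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_bwd(NumericVector gy, int H, int W) {
  IntegerVector yd = gy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2];
  std::vector<int> r0, r1, c0, c1; std::vector<double> rw, cw;
  lin_coords(H, Ho, r0, r1, rw);
  lin_coords(W, Wo, c0, c1, cw);
  NumericVector gx((R_xlen_t)H * W * C);
  for (int c = 0; c < C; ++c) {
    double* p = gx.begin() + (size_t)c * H * W;
    const double* q = gy.begin() + (size_t)c * Ho * Wo;
    for (int ow = 0; ow < Wo; ++ow) {
      double wc = cw[ow];
      for (int oh = 0; oh < Ho; ++oh) {
        double g = q[(size_t)ow * Ho + oh], wr = rw[oh];
        p[(size_t)c0[ow] * H + r0[oh]] += g * (1 - wc) * (1 - wr);
        p[(size_t)c1[ow] * H + r0[oh]] += g * wc * (1 - wr);
        p[(size_t)c0[ow] * H + r1[oh]] += g * (1 - wc) * wr;
        p[(size_t)c1[ow] * H + r1[oh]] += g * wc * wr;
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, C);
  return gx;
}
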