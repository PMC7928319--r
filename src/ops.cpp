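// Low-level tensor kernels for the CNN engine.
//
// All activations are dense double arrays with dim c(H, W, C, N) in R's
// column-major layout. Convolution weights are c(kh, kw, Cin, Cout).
// Stride is always 1 for convolutions (same-padding contract); spatial
// resampling is done by the dedicated pool/upconv/upsample kernels.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  SEXP da = x.attr("dim");
  if (Rf_isNull(da)) stop("expected a 4-d array (H, W, C, N)");
  IntegerVector d(da);
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// im2col for one sample. x points at an (H x W x C) block; K is
// (H*W) x (kh*kw*C): rows enumerate output pixels (i + H*j), columns
// match the column-major flattening of the weight array c(kh, kw, Cin,
// Cout), so the forward pass is the contiguous product K * Wmat.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int dil, int p0h, int p0w, arma::mat& K) {
  double* Kp = K.memptr();
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int iw_k = 0; iw_k < kw; ++iw_k) {
      for (int ih_k = 0; ih_k < kh; ++ih_k) {
        const size_t col = (size_t)(ih_k + kh * (iw_k + kw * c));
        double* Kcol = Kp + col * HW;
        const int di = ih_k * dil - p0h, dj = iw_k * dil - p0w;
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj;
          double* dst = Kcol + (size_t)j * H;
          if (jj < 0 || jj >= W) {
            std::fill(dst, dst + H, 0.0);
          } else {
            const double* xcol = xc + (size_t)jj * H;
            const int lo = std::max(0, -di), hi = std::min(H, H - di);
            if (lo > 0) std::fill(dst, dst + lo, 0.0);
            if (hi > lo) std::copy(xcol + lo + di, xcol + hi + di, dst + lo);
            if (hi < H) std::fill(dst + std::max(hi, lo), dst + H, 0.0);
          }
        }
      }
    }
  }
}

// transpose of im2col: scatter-add columns back into the image.
static void col2im_add(const arma::mat& K, int H, int W, int C,
                       int kh, int kw, int dil, int p0h, int p0w, double* gx) {
  const double* Kp = K.memptr();
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)c * H * W;
    for (int iw_k = 0; iw_k < kw; ++iw_k) {
      for (int ih_k = 0; ih_k < kh; ++ih_k) {
        const size_t col = (size_t)(ih_k + kh * (iw_k + kw * c));
        const double* Kcol = Kp + col * HW;
        const int di = ih_k * dil - p0h, dj = iw_k * dil - p0w;
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj;
          if (jj < 0 || jj >= W) continue;
          const double* src = Kcol + (size_t)j * H;
          double* gcol = gc + (size_t)jj * H;
          const int lo = std::max(0, -di), hi = std::min(H, H - di);
          for (int i = lo; i < hi; ++i) gcol[i + di] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int dil, int p0h, int p0w) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C)
    stop("channel mismatch: input has %d channels, kernel expects %d", C, Cin);
  const size_t HW = (size_t)H * W;
  NumericVector y(HW * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  arma::mat K(HW, kh * kw * Cin);
  NumericVector bb;
  const bool hasb = bias.isNotNull();
  if (hasb) bb = NumericVector(bias.get());
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * C, H, W, C, kh, kw, dil, p0h, p0w, K);
    arma::mat Y(y.begin() + (size_t)n * HW * Cout, HW, Cout, false, true);
    Y = K * Wm;
    if (hasb) for (int co = 0; co < Cout; ++co) Y.col(co) += bb[co];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    bool has_bias, int dil, int p0h, int p0w, bool need_gx) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const size_t HW = (size_t)H * W;
  const arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  arma::mat gW(kh * kw * Cin, Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  NumericVector gx;
  if (need_gx) {
    gx = NumericVector(HW * C * N);
    gx.attr("dim") = IntegerVector::create(H, W, C, N);
  }
  arma::mat K(HW, kh * kw * Cin);
  arma::mat Gcols;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * C, H, W, C, kh, kw, dil, p0h, p0w, K);
    const arma::mat G(const_cast<double*>(gy.begin()) + (size_t)n * HW * Cout,
                      HW, Cout, false, true);
    gW += K.t() * G;
    if (has_bias) gb += arma::sum(G, 0).t();
    if (need_gx) {
      Gcols = G * Wm.t();
      col2im_add(Gcols, H, W, C, kh, kw, dil, p0h, p0w,
                 gx.begin() + (size_t)n * HW * C);
    }
  }
  NumericVector gWr(gW.begin(), gW.end());
  gWr.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  List out = List::create(_["gW"] = gWr,
                          _["gb"] = has_bias ? wrap(NumericVector(gb.begin(), gb.end()))
                                             : R_NilValue,
                          _["gx"] = need_gx ? wrap(gx) : R_NilValue);
  return out;
}

// per-channel batch statistics over (H, W, N)
// [[Rcpp::export]]
List cpp_bn_stats(NumericVector x) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const size_t HW = (size_t)H * W;
  NumericVector mean(C), var(C);
  const double M = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + HW * ((size_t)c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    mean[c] = s / M;
    var[c] = s2 / M - mean[c] * mean[c];
    if (var[c] < 0) var[c] = 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// channelwise affine y = x * scale[c] + shift[c]
// [[Rcpp::export]]
NumericVector cpp_channel_affine(NumericVector x, NumericVector scale, NumericVector shift) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const size_t HW = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double sc = scale[c], sh = shift[c];
      const double* p = x.begin() + HW * ((size_t)c + (size_t)C * n);
      double* q = y.begin() + HW * ((size_t)c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) q[i] = p[i] * sc + sh;
    }
  return y;
}

// batch-norm backward (training mode, batch statistics)
// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector gy, NumericVector gamma,
                NumericVector mean, NumericVector invstd) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const size_t HW = (size_t)H * W;
  const double M = (double)HW * N;
  NumericVector gx(x.size()); gx.attr("dim") = x.attr("dim");
  NumericVector ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    double s1 = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + HW * ((size_t)c + (size_t)C * n);
      const double* pg = gy.begin() + HW * ((size_t)c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) {
        s1 += pg[i];
        s2 += pg[i] * (px[i] - mean[c]) * invstd[c];
      }
    }
    gbeta[c] = s1; ggamma[c] = s2;
    const double k = gamma[c] * invstd[c];
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + HW * ((size_t)c + (size_t)C * n);
      const double* pg = gy.begin() + HW * ((size_t)c + (size_t)C * n);
      double* pq = gx.begin() + HW * ((size_t)c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) {
        const double xhat = (px[i] - mean[c]) * invstd[c];
        pq[i] = k * (pg[i] - (s1 + xhat * s2) / M);
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// 2x2 max pooling, stride 2; idx stores the winning corner (0..3)
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("max-pool requires even spatial dims, got %d x %d", H, W);
  const int Ho = H / 2, Wo = W / 2;
  const size_t HWo = (size_t)Ho * Wo;
  NumericVector y(HWo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(HWo * C * N);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + (size_t)H * W * ((size_t)c + (size_t)C * n);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i, ++o) {
          const double* base = p + (size_t)(2 * j) * H + 2 * i;
          double v00 = base[0], v10 = base[1], v01 = base[H], v11 = base[H + 1];
          double best = v00; int k = 0;
          if (v10 > best) { best = v10; k = 1; }
          if (v01 > best) { best = v01; k = 2; }
          if (v11 > best) { best = v11; k = 3; }
          y[o] = best; idx[o] = k;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector gy, IntegerVector idx, int H, int W) {
  int Ho, Wo, C, N; get_dims4(gy, Ho, Wo, C, N);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* p = gx.begin() + (size_t)H * W * ((size_t)c + (size_t)C * n);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i, ++o) {
          const int k = idx[o];
          p[(size_t)(2 * j + (k >> 1)) * H + 2 * i + (k & 1)] += gy[o];
        }
    }
  return gx;
}

// transposed convolution, kernel 2x2, stride 2 (the U-Net "up-conv");
// non-overlapping, so each output 2x2 tile comes from one input pixel.
// weight layout c(2, 2, Cin, Cout)
// [[Rcpp::export]]
NumericVector cpp_upconv2_fwd(NumericVector x, NumericVector w, NumericVector bias) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch in up-conv");
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double* q = y.begin() + (size_t)Ho * Wo * ((size_t)co + (size_t)Cout * n);
      const double b = bias[co];
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) q[i] = b;
      for (int ci = 0; ci < C; ++ci) {
        const double* wp = w.begin() + 4 * ((size_t)ci + (size_t)Cin * co);
        const double w00 = wp[0], w10 = wp[1], w01 = wp[2], w11 = wp[3];
        const double* p = x.begin() + (size_t)H * W * ((size_t)ci + (size_t)C * n);
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            const double v = p[(size_t)j * H + i];
            double* t = q + (size_t)(2 * j) * Ho + 2 * i;
            t[0] += w00 * v; t[1] += w10 * v; t[Ho] += w01 * v; t[Ho + 1] += w11 * v;
          }
      }
    }
  return y;
}

// [[Rcpp::export]]
List cpp_upconv2_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int Cin = wd[2], Cout = wd[3];
  const int Ho = 2 * H;
  NumericVector gx(x.size()); gx.attr("dim") = x.attr("dim");
  NumericVector gW(w.size()); gW.attr("dim") = w.attr("dim");
  NumericVector gb(Cout);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* g = gy.begin() + (size_t)Ho * 2 * W * ((size_t)co + (size_t)Cout * n);
      double sb = 0.0;
      for (size_t i = 0; i < (size_t)Ho * 2 * W; ++i) sb += g[i];
      gb[co] += sb;
      for (int ci = 0; ci < C; ++ci) {
        const double* wp = w.begin() + 4 * ((size_t)ci + (size_t)Cin * co);
        double* gwp = gW.begin() + 4 * ((size_t)ci + (size_t)Cin * co);
        const double* p = x.begin() + (size_t)H * W * ((size_t)ci + (size_t)C * n);
        double* gp = gx.begin() + (size_t)H * W * ((size_t)ci + (size_t)C * n);
        double a00 = 0, a10 = 0, a01 = 0, a11 = 0;
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            const double v = p[(size_t)j * H + i];
            const double* t = g + (size_t)(2 * j) * Ho + 2 * i;
            a00 += t[0] * v; a10 += t[1] * v; a01 += t[Ho] * v; a11 += t[Ho + 1] * v;
            gp[(size_t)j * H + i] +=
              wp[0] * t[0] + wp[1] * t[1] + wp[2] * t[Ho] + wp[3] * t[Ho + 1];
          }
        gwp[0] += a00; gwp[1] += a10; gwp[2] += a01; gwp[3] += a11;
      }
    }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// factor-2 upsampling; method 0 = nearest, 1 = bilinear (half-pixel centers)
// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x, int method) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> i0(Ho), i1(Ho); std::vector<double> fw(Ho);
  for (int o = 0; o < Ho; ++o) {
    if (method == 0) { i0[o] = o / 2; i1[o] = o / 2; fw[o] = 0.0; }
    else {
      double s = (o + 0.5) / 2.0 - 0.5;
      int lo = (int)std::floor(s);
      double f = s - lo;
      if (lo < 0) { lo = 0; f = 0.0; }
      if (lo >= H - 1) { lo = H - 1; f = 0.0; }
      i0[o] = lo; i1[o] = std::min(lo + 1, H - 1); fw[o] = f;
    }
  }
  // same tables apply along W when H == W is not guaranteed: recompute for W
  std::vector<int> j0(Wo), j1(Wo); std::vector<double> gw(Wo);
  for (int o = 0; o < Wo; ++o) {
    if (method == 0) { j0[o] = o / 2; j1[o] = o / 2; gw[o] = 0.0; }
    else {
      double s = (o + 0.5) / 2.0 - 0.5;
      int lo = (int)std::floor(s);
      double f = s - lo;
      if (lo < 0) { lo = 0; f = 0.0; }
      if (lo >= W - 1) { lo = W - 1; f = 0.0; }
      j0[o] = lo; j1[o] = std::min(lo + 1, W - 1); gw[o] = f;
    }
  }
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + (size_t)H * W * ((size_t)c + (size_t)C * n);
      double* q = y.begin() + (size_t)Ho * Wo * ((size_t)c + (size_t)C * n);
      for (int oj = 0; oj < Wo; ++oj)
        for (int oi = 0; oi < Ho; ++oi) {
          const double f = fw[oi], g = gw[oj];
          const double v =
            (1 - f) * (1 - g) * p[(size_t)j0[oj] * H + i0[oi]] +
            f * (1 - g) * p[(size_t)j0[oj] * H + i1[oi]] +
            (1 - f) * g * p[(size_t)j1[oj] * H + i0[oi]] +
            f * g * p[(size_t)j1[oj] * H + i1[oi]];
          q[(size_t)oj * Ho + oi] = v;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector gy, int H, int W, int method) {
  int Ho, Wo, C, N; get_dims4(gy, Ho, Wo, C, N);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  std::vector<int> i0(Ho), i1(Ho); std::vector<double> fw(Ho);
  for (int o = 0; o < Ho; ++o) {
    if (method == 0) { i0[o] = o / 2; i1[o] = o / 2; fw[o] = 0.0; }
    else {
      double s = (o + 0.5) / 2.0 - 0.5;
      int lo = (int)std::floor(s); double f = s - lo;
      if (lo < 0) { lo = 0; f = 0.0; }
      if (lo >= H - 1) { lo = H - 1; f = 0.0; }
      i0[o] = lo; i1[o] = std::min(lo + 1, H - 1); fw[o] = f;
    }
  }
  std::vector<int> j0(Wo), j1(Wo); std::vector<double> gw(Wo);
  for (int o = 0; o < Wo; ++o) {
    if (method == 0) { j0[o] = o / 2; j1[o] = o / 2; gw[o] = 0.0; }
    else {
      double s = (o + 0.5) / 2.0 - 0.5;
      int lo = (int)std::floor(s); double f = s - lo;
      if (lo < 0) { lo = 0; f = 0.0; }
      if (lo >= W - 1) { lo = W - 1; f = 0.0; }
      j0[o] = lo; j1[o] = std::min(lo + 1, W - 1); gw[o] = f;
    }
  }
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* p = gx.begin() + (size_t)H * W * ((size_t)c + (size_t)C * n);
      const double* q = gy.begin() + (size_t)Ho * Wo * ((size_t)c + (size_t)C * n);
      for (int oj = 0; oj < Wo; ++oj)
        for (int oi = 0; oi < Ho; ++oi) {
          const double v = q[(size_t)oj * Ho + oi];
          const double f = fw[oi], g = gw[oj];
          p[(size_t)j0[oj] * H + i0[oi]] += (1 - f) * (1 - g) * v;
          p[(size_t)j0[oj] * H + i1[oi]] += f * (1 - g) * v;
          p[(size_t)j1[oj] * H + i0[oi]] += (1 - f) * g * v;
          p[(size_t)j1[oj] * H + i1[oi]] += f * g * v;
        }
    }
  return gx;
}
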