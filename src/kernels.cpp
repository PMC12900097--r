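// Low-level 3D convolution / pooling kernels.
//
// All feature maps are dense numeric arrays in R's column-major layout with
// dimensions [H, W, D, C]; index(h,w,d,c) = h + H*(w + W*(d + D*c)), 0-based.
// Dense conv weights are [k, k, k, Cin, Cout]; depth-wise weights [k, k, k, C].
// Stride-2 kernels use kernel 4, padding 1 (exact x2 down/up resampling).

#include <Rcpp.h>
using namespace Rcpp;

static inline R_xlen_t idx4(int h, int w, int d, int c, int H, int W, int D) {
  return (R_xlen_t)h + (R_xlen_t)H * ((R_xlen_t)w + (R_xlen_t)W * ((R_xlen_t)d + (R_xlen_t)D * c));
}

// ---------------------------------------------------------------- dense conv

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector dimx,
                             NumericVector wt, int cout, int k) {
  const int H = dimx[0], W = dimx[1], D = dimx[2], Cin = dimx[3];
  const int pad = (k - 1) / 2;
  NumericVector y((R_xlen_t)H * W * D * cout);
  const double *px = x.begin(), *pw = wt.begin();
  double *py = y.begin();
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int kd = 0; kd < k; ++kd)
        for (int kw = 0; kw < k; ++kw)
          for (int kh = 0; kh < k; ++kh) {
            const double wv =
              pw[kh + k * (kw + k * (kd + k * (ci + (R_xlen_t)Cin * co)))];
            if (wv == 0.0) continue;
            const int d0 = std::max(0, pad - kd), d1 = std::min(D, D + pad - kd);
            const int w0 = std::max(0, pad - kw), w1 = std::min(W, W + pad - kw);
            const int h0 = std::max(0, pad - kh), h1 = std::min(H, H + pad - kh);
            for (int d = d0; d < d1; ++d)
              for (int w = w0; w < w1; ++w) {
                const double *src = px + idx4(h0 + kh - pad, w + kw - pad, d + kd - pad, ci, H, W, D);
                double *dst = py + idx4(h0, w, d, co, H, W, D);
                for (int h = h0; h < h1; ++h) *dst++ += wv * *src++;
              }
          }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector dimx, NumericVector wt,
                    int cout, int k, NumericVector dy) {
  const int H = dimx[0], W = dimx[1], D = dimx[2], Cin = dimx[3];
  const int pad = (k - 1) / 2;
  NumericVector dx((R_xlen_t)H * W * D * Cin), dw(wt.size());
  const double *px = x.begin(), *pw = wt.begin(), *pdy = dy.begin();
  double *pdx = dx.begin(), *pdw = dw.begin();
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int kd = 0; kd < k; ++kd)
        for (int kw = 0; kw < k; ++kw)
          for (int kh = 0; kh < k; ++kh) {
            const R_xlen_t wi =
              kh + k * (kw + k * ((R_xlen_t)kd + k * (ci + (R_xlen_t)Cin * co)));
            const double wv = pw[wi];
            double acc = 0.0;
            const int d0 = std::max(0, pad - kd), d1 = std::min(D, D + pad - kd);
            const int w0 = std::max(0, pad - kw), w1 = std::min(W, W + pad - kw);
            const int h0 = std::max(0, pad - kh), h1 = std::min(H, H + pad - kh);
            for (int d = d0; d < d1; ++d)
              for (int w = w0; w < w1; ++w) {
                const double *sx = px + idx4(h0 + kh - pad, w + kw - pad, d + kd - pad, ci, H, W, D);
                double *sdx = pdx + idx4(h0 + kh - pad, w + kw - pad, d + kd - pad, ci, H, W, D);
                const double *sdy = pdy + idx4(h0, w, d, co, H, W, D);
                for (int h = h0; h < h1; ++h) {
                  acc += sx[h - h0] * sdy[h - h0];
                  sdx[h - h0] += wv * sdy[h - h0];
                }
              }
            pdw[wi] += acc;
          }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// ----------------------------------------------------------- depth-wise conv

// [[Rcpp::export]]
NumericVector cpp_dwconv3d_fwd(NumericVector x, IntegerVector dimx,
                               NumericVector wt, int k) {
  const int H = dimx[0], W = dimx[1], D = dimx[2], C = dimx[3];
  const int pad = (k - 1) / 2;
  NumericVector y((R_xlen_t)H * W * D * C);
  const double *px = x.begin(), *pw = wt.begin();
  double *py = y.begin();
  for (int c = 0; c < C; ++c)
    for (int kd = 0; kd < k; ++kd)
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh) {
          const double wv = pw[kh + k * (kw + k * ((R_xlen_t)kd + k * c))];
          const int d0 = std::max(0, pad - kd), d1 = std::min(D, D + pad - kd);
          const int w0 = std::max(0, pad - kw), w1 = std::min(W, W + pad - kw);
          const int h0 = std::max(0, pad - kh), h1 = std::min(H, H + pad - kh);
          for (int d = d0; d < d1; ++d)
            for (int w = w0; w < w1; ++w) {
              const double *src = px + idx4(h0 + kh - pad, w + kw - pad, d + kd - pad, c, H, W, D);
              double *dst = py + idx4(h0, w, d, c, H, W, D);
              for (int h = h0; h < h1; ++h) *dst++ += wv * *src++;
            }
        }
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv3d_bwd(NumericVector x, IntegerVector dimx, NumericVector wt,
                      int k, NumericVector dy) {
  const int H = dimx[0], W = dimx[1], D = dimx[2], C = dimx[3];
  const int pad = (k - 1) / 2;
  NumericVector dx(x.size()), dw(wt.size());
  const double *px = x.begin(), *pw = wt.begin(), *pdy = dy.begin();
  double *pdx = dx.begin(), *pdw = dw.begin();
  for (int c = 0; c < C; ++c)
    for (int kd = 0; kd < k; ++kd)
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh) {
          const R_xlen_t wi = kh + k * (kw + k * ((R_xlen_t)kd + k * c));
          const double wv = pw[wi];
          double acc = 0.0;
          const int d0 = std::max(0, pad - kd), d1 = std::min(D, D + pad - kd);
          const int w0 = std::max(0, pad - kw), w1 = std::min(W, W + pad - kw);
          const int h0 = std::max(0, pad - kh), h1 = std::min(H, H + pad - kh);
          for (int d = d0; d < d1; ++d)
            for (int w = w0; w < w1; ++w) {
              const double *sx = px + idx4(h0 + kh - pad, w + kw - pad, d + kd - pad, c, H, W, D);
              double *sdx = pdx + idx4(h0 + kh - pad, w + kw - pad, d + kd - pad, c, H, W, D);
              const double *sdy = pdy + idx4(h0, w, d, c, H, W, D);
              for (int h = h0; h < h1; ++h) {
                acc += sx[h - h0] * sdy[h - h0];
                sdx[h - h0] += wv * sdy[h - h0];
              }
            }
          pdw[wi] += acc;
        }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// ------------------------------------- depth-wise conv, kernel 4 stride 2 pad 1

// [[Rcpp::export]]
NumericVector cpp_dwconv3d_s2_fwd(NumericVector x, IntegerVector dimx,
                                  NumericVector wt) {
  const int H = dimx[0], W = dimx[1], D = dimx[2], C = dimx[3];
  const int Ho = H / 2, Wo = W / 2, Do = D / 2, k = 4, pad = 1;
  NumericVector y((R_xlen_t)Ho * Wo * Do * C);
  const double *px = x.begin(), *pw = wt.begin();
  double *py = y.begin();
  for (int c = 0; c < C; ++c)
    for (int d = 0; d < Do; ++d)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          double acc = 0.0;
          for (int kd = 0; kd < k; ++kd) {
            const int di = 2 * d + kd - pad;
            if (di < 0 || di >= D) continue;
            for (int kw = 0; kw < k; ++kw) {
              const int wi = 2 * w + kw - pad;
              if (wi < 0 || wi >= W) continue;
              for (int kh = 0; kh < k; ++kh) {
                const int hi = 2 * h + kh - pad;
                if (hi < 0 || hi >= H) continue;
                acc += pw[kh + k * (kw + k * ((R_xlen_t)kd + k * c))] *
                       px[idx4(hi, wi, di, c, H, W, D)];
              }
            }
          }
          py[idx4(h, w, d, c, Ho, Wo, Do)] = acc;
        }
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv3d_s2_bwd(NumericVector x, IntegerVector dimx, NumericVector wt,
                         NumericVector dy) {
  const int H = dimx[0], W = dimx[1], D = dimx[2], C = dimx[3];
  const int Ho = H / 2, Wo = W / 2, Do = D / 2, k = 4, pad = 1;
  NumericVector dx(x.size()), dw(wt.size());
  const double *px = x.begin(), *pw = wt.begin(), *pdy = dy.begin();
  double *pdx = dx.begin(), *pdw = dw.begin();
  for (int c = 0; c < C; ++c)
    for (int d = 0; d < Do; ++d)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          const double g = pdy[idx4(h, w, d, c, Ho, Wo, Do)];
          if (g == 0.0) continue;
          for (int kd = 0; kd < k; ++kd) {
            const int di = 2 * d + kd - pad;
            if (di < 0 || di >= D) continue;
            for (int kw = 0; kw < k; ++kw) {
              const int wi = 2 * w + kw - pad;
              if (wi < 0 || wi >= W) continue;
              for (int kh = 0; kh < k; ++kh) {
                const int hi = 2 * h + kh - pad;
                if (hi < 0 || hi >= H) continue;
                const R_xlen_t wj = kh + k * (kw + k * ((R_xlen_t)kd + k * c));
                pdx[idx4(hi, wi, di, c, H, W, D)] += pw[wj] * g;
                pdw[wj] += px[idx4(hi, wi, di, c, H, W, D)] * g;
              }
            }
          }
        }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// -------------------- transposed depth-wise conv, kernel 4 stride 2 pad 1 (x2 up)

// [[Rcpp::export]]
NumericVector cpp_dwconv3d_t2_fwd(NumericVector x, IntegerVector dimx,
                                  NumericVector wt) {
  const int H = dimx[0], W = dimx[1], D = dimx[2], C = dimx[3];
  const int Ho = 2 * H, Wo = 2 * W, Do = 2 * D, k = 4, pad = 1;
  NumericVector y((R_xlen_t)Ho * Wo * Do * C);
  const double *px = x.begin(), *pw = wt.begin();
  double *py = y.begin();
  for (int c = 0; c < C; ++c)
    for (int d = 0; d < D; ++d)
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double v = px[idx4(h, w, d, c, H, W, D)];
          if (v == 0.0) continue;
          for (int kd = 0; kd < k; ++kd) {
            const int dz = 2 * d + kd - pad;
            if (dz < 0 || dz >= Do) continue;
            for (int kw = 0; kw < k; ++kw) {
              const int wz = 2 * w + kw - pad;
              if (wz < 0 || wz >= Wo) continue;
              for (int kh = 0; kh < k; ++kh) {
                const int hz = 2 * h + kh - pad;
                if (hz < 0 || hz >= Ho) continue;
                py[idx4(hz, wz, dz, c, Ho, Wo, Do)] +=
                  pw[kh + k * (kw + k * ((R_xlen_t)kd + k * c))] * v;
              }
            }
          }
        }
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv3d_t2_bwd(NumericVector x, IntegerVector dimx, NumericVector wt,
                         NumericVector dy) {
  const int H = dimx[0], W = dimx[1], D = dimx[2], C = dimx[3];
  const int Ho = 2 * H, Wo = 2 * W, Do = 2 * D, k = 4, pad = 1;
  NumericVector dx(x.size()), dw(wt.size());
  const double *px = x.begin(), *pw = wt.begin(), *pdy = dy.begin();
  double *pdx = dx.begin(), *pdw = dw.begin();
  for (int c = 0; c < C; ++c)
    for (int d = 0; d < D; ++d)
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double v = px[idx4(h, w, d, c, H, W, D)];
          double acc = 0.0;
          for (int kd = 0; kd < k; ++kd) {
            const int dz = 2 * d + kd - pad;
            if (dz < 0 || dz >= Do) continue;
            for (int kw = 0; kw < k; ++kw) {
              const int wz = 2 * w + kw - pad;
              if (wz < 0 || wz >= Wo) continue;
              for (int kh = 0; kh < k; ++kh) {
                const int hz = 2 * h + kh - pad;
                if (hz < 0 || hz >= Ho) continue;
                const R_xlen_t wj = kh + k * (kw + k * ((R_xlen_t)kd + k * c));
                const double g = pdy[idx4(hz, wz, dz, c, Ho, Wo, Do)];
                acc += pw[wj] * g;
                pdw[wj] += v * g;
              }
            }
          }
          pdx[idx4(h, w, d, c, H, W, D)] = acc;
        }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// ------------------------------------------------------------------ max-pool

// [[Rcpp::export]]
List cpp_maxpool3d_fwd(NumericVector x, IntegerVector dimx, int r) {
  const int H = dimx[0], W = dimx[1], D = dimx[2], C = dimx[3];
  const int Ho = H / r, Wo = W / r, Do = D / r;
  NumericVector y((R_xlen_t)Ho * Wo * Do * C);
  IntegerVector amax(y.size());
  const double *px = x.begin();
  double *py = y.begin();
  int *pa = amax.begin();
  for (int c = 0; c < C; ++c)
    for (int d = 0; d < Do; ++d)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          double best = R_NegInf;
          R_xlen_t bi = -1;
          for (int kd = 0; kd < r; ++kd)
            for (int kw = 0; kw < r; ++kw)
              for (int kh = 0; kh < r; ++kh) {
                const R_xlen_t i =
                  idx4(r * h + kh, r * w + kw, r * d + kd, c, H, W, D);
                if (px[i] > best) { best = px[i]; bi = i; }
              }
          const R_xlen_t o = idx4(h, w, d, c, Ho, Wo, Do);
          py[o] = best;
          pa[o] = (int)bi; // volumes here are far below 2^31 elements
        }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bwd(NumericVector dy, IntegerVector argmax,
                                R_xlen_t nx) {
  NumericVector dx(nx);
  const double *pdy = dy.begin();
  const int *pa = argmax.begin();
  double *pdx = dx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) pdx[pa[i]] += pdy[i];
  return dx;
}
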