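// Low-level numeric kernels for the tensor core.
// Tensors are R arrays with dim c(C, H, W); conv weights dim c(Cout, Cin/g, k, k);
// transposed-conv weights dim c(Cin, Cout, k, k).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int outdim(int n, int k, int s, int p) { return (n + 2 * p - k) / s + 1; }

// im2col: x (C,H,W) -> (C*kh*kw) x (Ho*Wo), zero padding
static arma::mat im2col(const double* x, int C, int H, int W,
                        int kh, int kw, int s, int p, int Ho, int Wo) {
  arma::mat col(C * kh * kw, Ho * Wo, arma::fill::zeros);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int ocol = ho + Ho * wo;
      for (int j = 0; j < kw; ++j) {
        int wi = wo * s - p + j;
        if (wi < 0 || wi >= W) continue;
        for (int i = 0; i < kh; ++i) {
          int hi = ho * s - p + i;
          if (hi < 0 || hi >= H) continue;
          for (int c = 0; c < C; ++c)
            col(c + C * (i + kh * j), ocol) = x[c + C * (hi + H * wi)];
        }
      }
    }
  }
  return col;
}

static void col2im_add(const arma::mat& col, double* x, int C, int H, int W,
                       int kh, int kw, int s, int p, int Ho, int Wo) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int ocol = ho + Ho * wo;
      for (int j = 0; j < kw; ++j) {
        int wi = wo * s - p + j;
        if (wi < 0 || wi >= W) continue;
        for (int i = 0; i < kh; ++i) {
          int hi = ho * s - p + i;
          if (hi < 0 || hi >= H) continue;
          for (int c = 0; c < C; ++c)
            x[c + C * (hi + H * wi)] += col(c + C * (i + kh * j), ocol);
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w, Nullable<NumericVector> bias,
                         int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2];
  int Cout = wd[0], Cin_g = wd[1], kh = wd[2], kw = wd[3];
  if (C != Cin_g * groups) stop("conv2d: channel/group mismatch");
  if (Cout % groups != 0) stop("conv2d: Cout not divisible by groups");
  int Ho = outdim(H, kh, stride, pad), Wo = outdim(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: non-positive output size");
  int Cout_g = Cout / groups;
  NumericVector y(Cout * Ho * Wo);
  y.attr("dim") = IntegerVector::create(Cout, Ho, Wo);
  // weight as matrix per group: (Cout_g) x (Cin_g*kh*kw); weight layout dim
  // c(Cout, Cin_g, kh, kw) -> element (co,ci,i,j) at co + Cout*(ci + Cin_g*(i + kh*j))
  for (int g = 0; g < groups; ++g) {
    // slice input channels of this group into contiguous buffer
    std::vector<double> xg(Cin_g * H * W);
    for (int wI = 0; wI < W; ++wI)
      for (int hI = 0; hI < H; ++hI)
        for (int c = 0; c < Cin_g; ++c)
          xg[c + Cin_g * (hI + H * wI)] = x[(g * Cin_g + c) + C * (hI + H * wI)];
    arma::mat col = im2col(xg.data(), Cin_g, H, W, kh, kw, stride, pad, Ho, Wo);
    arma::mat Wm(Cout_g, Cin_g * kh * kw);
    for (int co = 0; co < Cout_g; ++co)
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i)
          for (int c = 0; c < Cin_g; ++c)
            Wm(co, c + Cin_g * (i + kh * j)) =
              w[(g * Cout_g + co) + Cout * (c + Cin_g * (i + kh * j))];
    arma::mat Y = Wm * col;  // Cout_g x (Ho*Wo)
    for (int ocol = 0; ocol < Ho * Wo; ++ocol)
      for (int co = 0; co < Cout_g; ++co)
        y[(g * Cout_g + co) + Cout * ocol] = Y(co, ocol);
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int ocol = 0; ocol < Ho * Wo; ++ocol)
      for (int co = 0; co < Cout; ++co)
        y[co + Cout * ocol] += b[co];
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_bwd_input(NumericVector gy, NumericVector w,
                                   int stride, int pad, int groups, int H, int W) {
  IntegerVector gd = gy.attr("dim"), wd = w.attr("dim");
  int Cout = gd[0], Ho = gd[1], Wo = gd[2];
  int Cin_g = wd[1], kh = wd[2], kw = wd[3];
  int Cout_g = Cout / groups, C = Cin_g * groups;
  NumericVector gx(C * H * W);
  gx.attr("dim") = IntegerVector::create(C, H, W);
  for (int g = 0; g < groups; ++g) {
    arma::mat Wm(Cout_g, Cin_g * kh * kw);
    for (int co = 0; co < Cout_g; ++co)
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i)
          for (int c = 0; c < Cin_g; ++c)
            Wm(co, c + Cin_g * (i + kh * j)) =
              w[(g * Cout_g + co) + Cout * (c + Cin_g * (i + kh * j))];
    arma::mat Gy(Cout_g, Ho * Wo);
    for (int ocol = 0; ocol < Ho * Wo; ++ocol)
      for (int co = 0; co < Cout_g; ++co)
        Gy(co, ocol) = gy[(g * Cout_g + co) + Cout * ocol];
    arma::mat colg = Wm.t() * Gy;  // (Cin_g*kh*kw) x (Ho*Wo)
    std::vector<double> xg(Cin_g * H * W, 0.0);
    col2im_add(colg, xg.data(), Cin_g, H, W, kh, kw, stride, pad, Ho, Wo);
    for (int wI = 0; wI < W; ++wI)
      for (int hI = 0; hI < H; ++hI)
        for (int c = 0; c < Cin_g; ++c)
          gx[(g * Cin_g + c) + C * (hI + H * wI)] = xg[c + Cin_g * (hI + H * wI)];
  }
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_bwd_weight(NumericVector gy, NumericVector x,
                                    int kh, int kw, int stride, int pad, int groups) {
  IntegerVector gd = gy.attr("dim"), xd = x.attr("dim");
  int Cout = gd[0], Ho = gd[1], Wo = gd[2];
  int C = xd[0], H = xd[1], W = xd[2];
  int Cin_g = C / groups, Cout_g = Cout / groups;
  NumericVector gw(Cout * Cin_g * kh * kw);
  gw.attr("dim") = IntegerVector::create(Cout, Cin_g, kh, kw);
  for (int g = 0; g < groups; ++g) {
    std::vector<double> xg(Cin_g * H * W);
    for (int wI = 0; wI < W; ++wI)
      for (int hI = 0; hI < H; ++hI)
        for (int c = 0; c < Cin_g; ++c)
          xg[c + Cin_g * (hI + H * wI)] = x[(g * Cin_g + c) + C * (hI + H * wI)];
    arma::mat col = im2col(xg.data(), Cin_g, H, W, kh, kw, stride, pad, Ho, Wo);
    arma::mat Gy(Cout_g, Ho * Wo);
    for (int ocol = 0; ocol < Ho * Wo; ++ocol)
      for (int co = 0; co < Cout_g; ++co)
        Gy(co, ocol) = gy[(g * Cout_g + co) + Cout * ocol];
    arma::mat Gw = Gy * col.t();  // Cout_g x (Cin_g*kh*kw)
    for (int co = 0; co < Cout_g; ++co)
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i)
          for (int c = 0; c < Cin_g; ++c)
            gw[(g * Cout_g + co) + Cout * (c + Cin_g * (i + kh * j))] =
              Gw(co, c + Cin_g * (i + kh * j));
  }
  return gw;
}

// Transposed convolution, groups = 1. weight dim c(Cin, Cout, k, k).
// [[Rcpp::export]]
NumericVector cpp_convT2d(NumericVector x, NumericVector w, Nullable<NumericVector> bias,
                          int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2];
  int Cin = wd[0], Cout = wd[1], kh = wd[2], kw = wd[3];
  if (C != Cin) stop("convT2d: channel mismatch");
  int Ho = (H - 1) * stride - 2 * pad + kh, Wo = (W - 1) * stride - 2 * pad + kw;
  if (Ho < 1 || Wo < 1) stop("convT2d: non-positive output size");
  NumericVector y(Cout * Ho * Wo);
  y.attr("dim") = IntegerVector::create(Cout, Ho, Wo);
  for (int wi = 0; wi < W; ++wi)
    for (int hi = 0; hi < H; ++hi)
      for (int j = 0; j < kw; ++j) {
        int wo = wi * stride - pad + j;
        if (wo < 0 || wo >= Wo) continue;
        for (int i = 0; i < kh; ++i) {
          int ho = hi * stride - pad + i;
          if (ho < 0 || ho >= Ho) continue;
          for (int co = 0; co < Cout; ++co) {
            double acc = 0.0;
            for (int ci = 0; ci < Cin; ++ci)
              acc += x[ci + C * (hi + H * wi)] *
                     w[ci + Cin * (co + Cout * (i + kh * j))];
            y[co + Cout * (ho + Ho * wo)] += acc;
          }
        }
      }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int ocol = 0; ocol < Ho * Wo; ++ocol)
      for (int co = 0; co < Cout; ++co)
        y[co + Cout * ocol] += b[co];
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_convT2d_bwd_input(NumericVector gy, NumericVector w,
                                    int stride, int pad, int H, int W) {
  IntegerVector gd = gy.attr("dim"), wd = w.attr("dim");
  int Cout = gd[0], Ho = gd[1], Wo = gd[2];
  int Cin = wd[0], kh = wd[2], kw = wd[3];
  NumericVector gx(Cin * H * W);
  gx.attr("dim") = IntegerVector::create(Cin, H, W);
  for (int wi = 0; wi < W; ++wi)
    for (int hi = 0; hi < H; ++hi)
      for (int j = 0; j < kw; ++j) {
        int wo = wi * stride - pad + j;
        if (wo < 0 || wo >= Wo) continue;
        for (int i = 0; i < kh; ++i) {
          int ho = hi * stride - pad + i;
          if (ho < 0 || ho >= Ho) continue;
          for (int ci = 0; ci < Cin; ++ci) {
            double acc = 0.0;
            for (int co = 0; co < Cout; ++co)
              acc += gy[co + Cout * (ho + Ho * wo)] *
                     w[ci + Cin * (co + Cout * (i + kh * j))];
            gx[ci + Cin * (hi + H * wi)] += acc;
          }
        }
      }
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_convT2d_bwd_weight(NumericVector gy, NumericVector x,
                                     int kh, int kw, int stride, int pad) {
  IntegerVector gd = gy.attr("dim"), xd = x.attr("dim");
  int Cout = gd[0], Ho = gd[1], Wo = gd[2];
  int Cin = xd[0], H = xd[1], W = xd[2];
  NumericVector gw(Cin * Cout * kh * kw);
  gw.attr("dim") = IntegerVector::create(Cin, Cout, kh, kw);
  for (int wi = 0; wi < W; ++wi)
    for (int hi = 0; hi < H; ++hi)
      for (int j = 0; j < kw; ++j) {
        int wo = wi * stride - pad + j;
        if (wo < 0 || wo >= Wo) continue;
        for (int i = 0; i < kh; ++i) {
          int ho = hi * stride - pad + i;
          if (ho < 0 || ho >= Ho) continue;
          for (int co = 0; co < Cout; ++co)
            for (int ci = 0; ci < Cin; ++ci)
              gw[ci + Cin * (co + Cout * (i + kh * j))] +=
                x[ci + Cin * (hi + H * wi)] * gy[co + Cout * (ho + Ho * wo)];
        }
      }
  return gw;
}

// Max pooling with argmax (for SPPF). Padding uses -inf.
// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2];
  int Ho = outdim(H, k, stride, pad), Wo = outdim(W, k, stride, pad);
  NumericVector y(C * Ho * Wo);
  IntegerVector arg(C * Ho * Wo);
  y.attr("dim") = IntegerVector::create(C, Ho, Wo);
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int c = 0; c < C; ++c) {
        double best = -INFINITY; int bidx = -1;
        for (int j = 0; j < k; ++j) {
          int wi = wo * stride - pad + j;
          if (wi < 0 || wi >= W) continue;
          for (int i = 0; i < k; ++i) {
            int hi = ho * stride - pad + i;
            if (hi < 0 || hi >= H) continue;
            double v = x[c + C * (hi + H * wi)];
            if (v > best) { best = v; bidx = c + C * (hi + H * wi); }
          }
        }
        y[c + C * (ho + Ho * wo)] = best;
        arg[c + C * (ho + Ho * wo)] = bidx;
      }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gy, IntegerVector argmax, int C, int H, int W) {
  NumericVector gx(C * H * W);
  gx.attr("dim") = IntegerVector::create(C, H, W);
  for (int i = 0; i < gy.size(); ++i)
    if (argmax[i] >= 0) gx[argmax[i]] += gy[i];
  return gx;
}

// 2-D correlation of a single-channel image (H x W matrix) with an arbitrary
// kernel, reflect border (edge pixel not repeated: index -1 -> 1).
// [[Rcpp::export]]
NumericMatrix cpp_filter2_reflect(NumericMatrix img, NumericMatrix ker) {
  int H = img.nrow(), W = img.ncol(), kh = ker.nrow(), kw = ker.ncol();
  int ch = kh / 2, cw = kw / 2;
  NumericMatrix out(H, W);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double acc = 0.0;
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i) {
          int hi = h + i - ch, wi = w + j - cw;
          if (hi < 0) hi = -hi; else if (hi >= H) hi = 2 * H - 2 - hi;
          if (wi < 0) wi = -wi; else if (wi >= W) wi = 2 * W - 2 - wi;
          acc += img(hi, wi) * ker(i, j);
        }
      out(h, w) = acc;
    }
  return out;
}

// IEEE-754 binary16 pack/unpack (round-to-nearest-even).
static uint16_t f32_to_f16(float f) {
  uint32_t x; memcpy(&x, &f, 4);
  uint32_t sign = (x >> 16) & 0x8000u;
  int32_t exp = ((x >> 23) & 0xFF) - 127 + 15;
  uint32_t mant = x & 0x7FFFFFu;
  if (((x >> 23) & 0xFF) == 0xFF) return sign | 0x7C00u | (mant ? 0x200u : 0);
  if (exp >= 31) return sign | 0x7C00u;                 // overflow -> inf
  if (exp <= 0) {                                        // subnormal / zero
    if (exp < -10) return sign;
    mant |= 0x800000u;
    int shift = 14 - exp;
    uint32_t half = mant >> shift;
    uint32_t rem = mant & ((1u << shift) - 1), mid = 1u << (shift - 1);
    if (rem > mid || (rem == mid && (half & 1))) half++;
    return sign | half;
  }
  uint32_t half = sign | (exp << 10) | (mant >> 13);
  uint32_t rem = mant & 0x1FFFu;
  if (rem > 0x1000u || (rem == 0x1000u && (half & 1))) half++;
  return half;
}

static float f16_to_f32(uint16_t h) {
  uint32_t sign = (uint32_t)(h & 0x8000u) << 16;
  uint32_t exp = (h >> 10) & 0x1F, mant = h & 0x3FFu;
  uint32_t x;
  if (exp == 0) {
    if (mant == 0) x = sign;
    else {
      exp = 127 - 15 + 1;
      while (!(mant & 0x400u)) { mant <<= 1; exp--; }
      mant &= 0x3FFu;
      x = sign | (exp << 23) | (mant << 13);
    }
  } else if (exp == 31) {
    x = sign | 0x7F800000u | (mant << 13);
  } else {
    x = sign | ((exp - 15 + 127) << 23) | (mant << 13);
  }
  float f; memcpy(&f, &x, 4);
  return f;
}

// [[Rcpp::export]]
RawVector cpp_fp16_pack(NumericVector v) {
  RawVector out(v.size() * 2);
  for (int i = 0; i < v.size(); ++i) {
    uint16_t h = f32_to_f16((float)v[i]);
    out[2 * i] = h & 0xFF;
    out[2 * i + 1] = (h >> 8) & 0xFF;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_fp16_unpack(RawVector r) {
  int n = r.size() / 2;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    uint16_t h = (uint16_t)r[2 * i] | ((uint16_t)r[2 * i + 1] << 8);
    out[i] = f16_to_f32(h);
  }
  return out;
}
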