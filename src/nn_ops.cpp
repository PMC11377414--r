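// Low-level numeric kernels for the connected U-Net.
//
// Tensor layout everywhere: column-major R arrays with dim (H, W, C, N),
// i.e. element (h, w, c, n) sits at offset h + H*(w + W*(c + C*n)).
// Convolution weights are (kh, kw, Cin, Cout); a reshaped view with row
// index a + kh*b + kh*kw*c is therefore the (kh*kw*Cin, Cout) matrix used
// in the im2col GEMM formulation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  return d;
}

// Fill the im2col matrix, laid out (H*W, K) so that for each tap r the
// H*W column is written with unit stride over h. Out-of-range taps stay 0.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int pad, arma::mat& col) {
  const int K = kh * kw * C;
  const size_t HW = (size_t)H * W;
  col.zeros(HW, K);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int b = 0; b < kw; ++b) {
      for (int a = 0; a < kh; ++a) {
        const int r = a + kh * b + kh * kw * c;
        double* dcol = col.colptr(r);
        const int h0 = std::max(0, pad - a);
        const int h1 = std::min(H, H + pad - a);
        for (int w = 0; w < W; ++w) {
          const int iw = w + b - pad;
          if (iw < 0 || iw >= W) continue;
          const double* src = xc + (size_t)H * iw + (h0 + a - pad);
          std::copy(src, src + (h1 - h0), dcol + (size_t)H * w + h0);
        }
      }
    }
  }
}

// Scatter-accumulate an (H*W, K) column matrix back onto the input grid.
static void col2im(const arma::mat& col, int H, int W, int C,
                   int kh, int kw, int pad, double* gx) {
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)H * W * c;
    for (int b = 0; b < kw; ++b) {
      for (int a = 0; a < kh; ++a) {
        const int r = a + kh * b + kh * kw * c;
        const double* scol = col.colptr(r);
        const int h0 = std::max(0, pad - a);
        const int h1 = std::min(H, H + pad - a);
        for (int w = 0; w < W; ++w) {
          const int iw = w + b - pad;
          if (iw < 0 || iw >= W) continue;
          double* dst = gc + (size_t)H * iw + (h0 + a - pad);
          const double* src = scol + (size_t)H * w + h0;
          for (int h = 0; h < h1 - h0; ++h) dst[h] += src[h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector wt,
                             NumericVector bias, int pad) {
  IntegerVector dx = dims4(x), dw = dims4(wt);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cin = dw[2], Cout = dw[3];
  if (Cin != C) stop("conv2d: input has %d channels, kernel expects %d", C, Cin);
  if (bias.size() != Cout) stop("conv2d: bias length mismatch");
  const int K = kh * kw * Cin;
  const size_t HW = (size_t)H * W;

  NumericVector y(HW * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wm(const_cast<double*>(wt.begin()), K, Cout, false, true);
  arma::rowvec bv(const_cast<double*>(bias.begin()), Cout, false, true);

  arma::mat col;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + HW * C * n;
    double* yn = y.begin() + HW * Cout * n;
    arma::mat Yn(yn, HW, Cout, false, true);
    if (kh == 1 && kw == 1 && pad == 0) {
      arma::mat Xn(const_cast<double*>(xn), HW, Cin, false, true);
      Yn = Xn * Wm;
    } else {
      im2col(xn, H, W, C, kh, kw, pad, col);
      Yn = col * Wm;
    }
    Yn.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector wt, NumericVector gy,
                    int pad) {
  IntegerVector dx = dims4(x), dw = dims4(wt);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cin = dw[2], Cout = dw[3];
  const int K = kh * kw * Cin;
  const size_t HW = (size_t)H * W;

  NumericVector gx(x.size());
  gx.attr("dim") = dx;
  NumericVector gw(wt.size());
  gw.attr("dim") = dw;
  NumericVector gb(Cout);
  arma::mat Wm(const_cast<double*>(wt.begin()), K, Cout, false, true);
  arma::mat Gw(gw.begin(), K, Cout, false, true);
  arma::rowvec Gb(gb.begin(), Cout, false, true);

  arma::mat col, gcol;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + HW * C * n;
    arma::mat Gy(const_cast<double*>(gy.begin()) + HW * Cout * n,
                 HW, Cout, false, true);
    double* gxn = gx.begin() + HW * C * n;
    if (kh == 1 && kw == 1 && pad == 0) {
      arma::mat Xn(const_cast<double*>(xn), HW, Cin, false, true);
      arma::mat Gx(gxn, HW, Cin, false, true);
      Gw += Xn.t() * Gy;
      Gx += Gy * Wm.t();
    } else {
      im2col(xn, H, W, C, kh, kw, pad, col);
      Gw += col.t() * Gy;
      gcol = Gy * Wm.t();
      col2im(gcol, H, W, C, kh, kw, pad, gxn);
    }
    Gb += arma::sum(Gy, 0);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transposed convolution, 2x2 kernel, stride 2: exact inverse geometry of
// the 2x2 pooling, doubling both spatial dims.
// [[Rcpp::export]]
NumericVector tconv2d_fwd_cpp(NumericVector x, NumericVector wt,
                              NumericVector bias) {
  IntegerVector dx = dims4(x), dw = dims4(wt);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  if (dw[0] != 2 || dw[1] != 2) stop("tconv2d: kernel must be 2x2");
  const int Cin = dw[2], Cout = dw[3];
  if (Cin != C) stop("tconv2d: channel mismatch");
  const int Ho = 2 * H, Wo = 2 * W;
  const size_t HW = (size_t)H * W, HWo = (size_t)Ho * Wo;

  NumericVector y(HWo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  // unpack the four (Cin x Cout) tap matrices
  arma::mat Wab[4];
  for (int b = 0; b < 2; ++b)
    for (int a = 0; a < 2; ++a) {
      arma::mat m(Cin, Cout);
      for (int o = 0; o < Cout; ++o)
        for (int c = 0; c < Cin; ++c)
          m(c, o) = wt[a + 2 * (b + 2 * (c + (size_t)Cin * o))];
      Wab[a + 2 * b] = m;
    }

  arma::mat Y;
  for (int n = 0; n < N; ++n) {
    arma::mat Xn(const_cast<double*>(x.begin()) + HW * C * n, HW, Cin,
                 false, true);
    double* yn = y.begin() + HWo * Cout * n;
    for (int b = 0; b < 2; ++b)
      for (int a = 0; a < 2; ++a) {
        Y = Xn * Wab[a + 2 * b];
        for (int o = 0; o < Cout; ++o) {
          const double bo = bias[o];
          for (int w = 0; w < W; ++w) {
            const double* src = Y.colptr(o) + (size_t)H * w;
            double* dst = yn + (size_t)HWo * o + (size_t)Ho * (2 * w + b) + a;
            for (int h = 0; h < H; ++h) dst[2 * h] = src[h] + bo;
          }
        }
      }
  }
  return y;
}

// [[Rcpp::export]]
List tconv2d_bwd_cpp(NumericVector x, NumericVector wt, NumericVector gy) {
  IntegerVector dx = dims4(x), dw = dims4(wt);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int Cin = dw[2], Cout = dw[3];
  const int Ho = 2 * H, Wo = 2 * W;
  const size_t HW = (size_t)H * W, HWo = (size_t)Ho * Wo;

  NumericVector gx(x.size());
  gx.attr("dim") = dx;
  NumericVector gw(wt.size());
  gw.attr("dim") = dw;
  NumericVector gb(Cout);

  arma::mat Wab[4];
  for (int b = 0; b < 2; ++b)
    for (int a = 0; a < 2; ++a) {
      arma::mat m(Cin, Cout);
      for (int o = 0; o < Cout; ++o)
        for (int c = 0; c < Cin; ++c)
          m(c, o) = wt[a + 2 * (b + 2 * (c + (size_t)Cin * o))];
      Wab[a + 2 * b] = m;
    }
  arma::mat GWab[4];
  for (int k = 0; k < 4; ++k) GWab[k].zeros(Cin, Cout);

  arma::mat G(HW, Cout);
  for (int n = 0; n < N; ++n) {
    arma::mat Xn(const_cast<double*>(x.begin()) + HW * C * n, HW, Cin,
                 false, true);
    arma::mat Gx(gx.begin() + HW * C * n, HW, Cin, false, true);
    const double* gyn = gy.begin() + HWo * Cout * n;
    for (int b = 0; b < 2; ++b)
      for (int a = 0; a < 2; ++a) {
        for (int o = 0; o < Cout; ++o) {
          double acc = 0.0;
          for (int w = 0; w < W; ++w) {
            const double* src =
              gyn + (size_t)HWo * o + (size_t)Ho * (2 * w + b) + a;
            double* dst = G.colptr(o) + (size_t)H * w;
            for (int h = 0; h < H; ++h) {
              dst[h] = src[2 * h];
              acc += src[2 * h];
            }
          }
          gb[o] += acc;
        }
        Gx += G * Wab[a + 2 * b].t();
        GWab[a + 2 * b] += Xn.t() * G;
      }
  }
  for (int b = 0; b < 2; ++b)
    for (int a = 0; a < 2; ++a)
      for (int o = 0; o < Cout; ++o)
        for (int c = 0; c < Cin; ++c)
          gw[a + 2 * (b + 2 * (c + (size_t)Cin * o))] = GWab[a + 2 * b](c, o);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Returns the pooled map and, for the backward
// pass, the 1-based linear index (into the input array) of each maximum.
// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x) {
  IntegerVector dx = dims4(x);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  if (H % 2 || W % 2) stop("maxpool2: spatial dims must be even, got %dx%d", H, W);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());

  size_t j = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          size_t i00 = base + (size_t)H * (2 * w) + 2 * h;
          size_t cand[4] = {i00, i00 + 1, i00 + (size_t)H, i00 + (size_t)H + 1};
          size_t best = cand[0];
          double bv = x[cand[0]];
          for (int k = 1; k < 4; ++k)
            if (x[cand[k]] > bv) { bv = x[cand[k]]; best = cand[k]; }
          y[j] = bv;
          idx[j] = (int)(best + 1);
          ++j;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector gy, IntegerVector idx,
                               IntegerVector in_dim) {
  size_t sz = (size_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3];
  NumericVector gx(sz);
  gx.attr("dim") = in_dim;
  for (R_xlen_t j = 0; j < gy.size(); ++j) gx[idx[j] - 1] += gy[j];
  return gx;
}

// For each row of A (points, in mm), the distance to the nearest row of B.
// Streaming O(n*m); used for 95th-percentile symmetric surface distance.
// [[Rcpp::export]]
NumericVector min_pair_dists_cpp(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow(), d = A.ncol();
  if (B.ncol() != d) stop("dimension mismatch");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = A(i, k) - B(j, k);
        s += diff * diff;
      }
      if (s < best) best = s;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Fused instance normalization (per channel-and-sample statistics over the
// spatial plane, population variance, affine terms) + LeakyReLU. Returns
// the activation plus the normalized tensor and std needed for backward.
// [[Rcpp::export]]
List in_lrelu_fwd_cpp(NumericVector x, NumericVector gamma,
                      NumericVector beta, double slope, double eps) {
  IntegerVector dx = dims4(x);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const size_t P = (size_t)H * W;
  NumericVector y(x.size()), xhat(x.size());
  y.attr("dim") = dx;
  NumericVector stdv((size_t)C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + P * (c + (size_t)C * n);
      double* yp = y.begin() + P * (c + (size_t)C * n);
      double* hp = xhat.begin() + P * (c + (size_t)C * n);
      double s = 0, s2 = 0;
      for (size_t i = 0; i < P; ++i) { s += xp[i]; s2 += xp[i] * xp[i]; }
      const double mu = s / P;
      double va = s2 / P - mu * mu;
      if (va < 0) va = 0;
      const double sd = std::sqrt(va + eps);
      stdv[c + (size_t)C * n] = sd;
      const double g = gamma[c], be = beta[c];
      for (size_t i = 0; i < P; ++i) {
        const double xh = (xp[i] - mu) / sd;
        hp[i] = xh;
        const double pre = g * xh + be;
        yp[i] = pre > 0 ? pre : slope * pre;
      }
    }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["std"] = stdv);
}

// [[Rcpp::export]]
List in_lrelu_bwd_cpp(NumericVector gy, NumericVector xhat,
                      NumericVector stdv, NumericVector gamma,
                      NumericVector beta, double slope) {
  IntegerVector dx = dims4(gy);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const size_t P = (size_t)H * W;
  NumericVector gx(gy.size());
  gx.attr("dim") = dx;
  NumericVector gg(C), gb(C);
  std::vector<double> gxh(P);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = P * (c + (size_t)C * n);
      const double* gp = gy.begin() + off;
      const double* hp = xhat.begin() + off;
      double* op = gx.begin() + off;
      const double g = gamma[c], be = beta[c], sd = stdv[c + (size_t)C * n];
      double sg = 0, sgh = 0;
      for (size_t i = 0; i < P; ++i) {
        const double pre = g * hp[i] + be;
        const double gpre = gp[i] * (pre > 0 ? 1.0 : slope);
        gxh[i] = gpre;
        sg += gpre;
        sgh += gpre * hp[i];
      }
      gg[c] += sgh;
      gb[c] += sg;
      const double m1 = sg / P * g, m2 = sgh / P * g;
      for (size_t i = 0; i < P; ++i)
        op[i] = (gxh[i] * g - m1 - hp[i] * m2) / sd;
    }
  return List::create(_["gx"] = gx, _["ggamma"] = gg, _["gbeta"] = gb);
}
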