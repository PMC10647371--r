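// Low-level kernels for the two-channel CNN and for segmentation labeling.
//
// Activation layout: one sample per column, flattened (H, W, C) column-major,
// i.e. index = h + H*(w + W*c). Conv weights are (KH*KW*Cin) x Cout with row
// index kh + KH*(kw + KW*ci). Convolutions are stride-1 with zero padding
// (pad = (K-1)/2, "same" output size). 1-D convolutions reuse the 2-D path
// with H = 1, KH = 1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C,
                   int KH, int KW, int padH, int padW, arma::mat& P) {
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        const int col = kh + KH * (kw + KW * c);
        double* pc = P.colptr(col);
        const int dh = kh - padH;
        for (int w = 0; w < W; ++w) {
          const int iw = w + kw - padW;
          double* dst = pc + (std::size_t)H * w;
          if (iw < 0 || iw >= W) {
            std::fill(dst, dst + H, 0.0);
            continue;
          }
          const double* src = x + (std::size_t)H * (iw + (std::size_t)W * c);
          const int h0 = std::max(0, -dh);
          const int h1 = std::min(H, H - dh);
          if (h0 > 0) std::fill(dst, dst + h0, 0.0);
          for (int h = h0; h < h1; ++h) dst[h] = src[h + dh];
          if (h1 < H) std::fill(dst + std::max(h1, 0), dst + H, 0.0);
        }
      }
    }
  }
  (void)HW;
}

// [[Rcpp::export]]
NumericMatrix cpp_conv2d_fw(NumericMatrix X, int H, int W, int C,
                            NumericMatrix Wk, NumericVector bias,
                            int KH, int KW) {
  const int B = X.ncol();
  const int Cout = Wk.ncol();
  const int padH = (KH - 1) / 2, padW = (KW - 1) / 2;
  const int HW = H * W;
  NumericMatrix Y(HW * Cout, B);
  arma::mat P(HW, KH * KW * C);
  arma::mat Wm(Wk.begin(), Wk.nrow(), Cout, false);
  for (int b = 0; b < B; ++b) {
    im2col(&X(0, b), H, W, C, KH, KW, padH, padW, P);
    arma::mat Ys(&Y(0, b), HW, Cout, false, true);
    Ys = P * Wm;
    for (int co = 0; co < Cout; ++co) Ys.col(co) += bias[co];
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericMatrix X, NumericMatrix dY, int H, int W, int C,
                   NumericMatrix Wk, int KH, int KW, bool need_dx) {
  const int B = X.ncol();
  const int Cout = Wk.ncol();
  const int K = Wk.nrow();
  const int padH = (KH - 1) / 2, padW = (KW - 1) / 2;
  const int HW = H * W;
  arma::mat P(HW, K);
  arma::mat Wm(Wk.begin(), K, Cout, false);
  arma::mat dW(K, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  NumericMatrix dX(need_dx ? X.nrow() : 1, need_dx ? B : 1);
  arma::mat dP;
  if (need_dx) dP.set_size(HW, K);
  for (int b = 0; b < B; ++b) {
    im2col(&X(0, b), H, W, C, KH, KW, padH, padW, P);
    arma::mat dYs((double*)&dY(0, b), HW, Cout, false);
    dW += P.t() * dYs;
    db += arma::sum(dYs, 0).t();
    if (need_dx) {
      dP = dYs * Wm.t();
      double* dx = &dX(0, b);
      std::fill(dx, dx + X.nrow(), 0.0);
      for (int c = 0; c < C; ++c)
        for (int kw = 0; kw < KW; ++kw)
          for (int kh = 0; kh < KH; ++kh) {
            const int col = kh + KH * (kw + KW * c);
            const double* pc = dP.colptr(col);
            const int dh = kh - padH;
            for (int w = 0; w < W; ++w) {
              const int iw = w + kw - padW;
              if (iw < 0 || iw >= W) continue;
              double* dst = dx + (std::size_t)H * (iw + (std::size_t)W * c);
              const double* src = pc + (std::size_t)H * w;
              const int h0 = std::max(0, -dh);
              const int h1 = std::min(H, H - dh);
              for (int h = h0; h < h1; ++h) dst[h + dh] += src[h];
            }
          }
    }
  }
  return List::create(_["dW"] = wrap(dW), _["db"] = wrap(db),
                      _["dX"] = need_dx ? dX : NumericMatrix(0, 0));
}

// Fused batch-norm + ReLU + max-pool over one conv block's output.
// Per-channel moments are taken over spatial x batch positions. The pool
// records the argmax of the (monotone) normalized value per window, or -1
// when the window's ReLU output is 0, so the backward pass can recompute
// everything from the raw conv output without storing normalized copies.
// [[Rcpp::export]]
List cpp_bnpool_fw(NumericMatrix X, int H, int W, int C,
                   NumericVector gamma, NumericVector beta, double eps,
                   bool training, NumericVector run_mean,
                   NumericVector run_var, int ph, int pw) {
  const int B = X.ncol();
  const int HW = H * W;
  const int Ho = H / ph, Wo = W / pw;
  NumericMatrix Y(Ho * Wo * C, B);
  IntegerMatrix idx(Ho * Wo * C, B);
  NumericVector mean(C), var(C), invstd(C);
  if (training) {
    const double N = (double)HW * B;
    for (int c = 0; c < C; ++c) {
      double s = 0.0, s2 = 0.0;
      for (int b = 0; b < B; ++b) {
        const double* xb = &X(0, b) + (std::size_t)HW * c;
        for (int i = 0; i < HW; ++i) { s += xb[i]; s2 += xb[i] * xb[i]; }
      }
      const double mu = s / N;
      double v = s2 / N - mu * mu;
      if (v < 0) v = 0;
      mean[c] = mu; var[c] = v;
      invstd[c] = 1.0 / std::sqrt(v + eps);
    }
  } else {
    for (int c = 0; c < C; ++c) {
      mean[c] = run_mean[c];
      var[c] = run_var[c];
      invstd[c] = 1.0 / std::sqrt(run_var[c] + eps);
    }
  }
  for (int b = 0; b < B; ++b) {
    const double* xb = &X(0, b);
    double* yb = &Y(0, b);
    int* ib = &idx(0, b);
    for (int c = 0; c < C; ++c) {
      const double g = gamma[c], bt = beta[c], mu = mean[c], is = invstd[c];
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -HUGE_VAL; int bi = -1;
          for (int dw = 0; dw < pw; ++dw)
            for (int dh = 0; dh < ph; ++dh) {
              const int h = ho * ph + dh, w = wo * pw + dw;
              const std::size_t k =
                h + (std::size_t)H * (w + (std::size_t)W * c);
              const double v = g * (xb[k] - mu) * is + bt;
              if (v > best) { best = v; bi = (int)k; }
            }
          const std::size_t o =
            ho + (std::size_t)Ho * (wo + (std::size_t)Wo * c);
          if (best > 0.0) { yb[o] = best; ib[o] = bi; }
          else { yb[o] = 0.0; ib[o] = -1; }
        }
    }
  }
  return List::create(_["y"] = Y, _["idx"] = idx, _["mean"] = mean,
                      _["var"] = var, _["invstd"] = invstd);
}

// [[Rcpp::export]]
List cpp_bnpool_bw(NumericMatrix X, NumericMatrix dY, IntegerMatrix idx,
                   NumericVector mean, NumericVector invstd,
                   NumericVector gamma, int H, int W, int C,
                   int ph, int pw) {
  const int B = X.ncol();
  const int HW = H * W;
  const int Ho = H / ph, Wo = W / pw;
  const int HWo = Ho * Wo;
  const double N = (double)HW * B;
  NumericMatrix dX(X.nrow(), B);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double mu = mean[c], is = invstd[c];
    double sdy = 0.0, sdyx = 0.0;
    for (int b = 0; b < B; ++b) {
      const double* dyb = &dY(0, b) + (std::size_t)HWo * c;
      const int* ib = &idx(0, b) + (std::size_t)HWo * c;
      const double* xb = &X(0, b);
      for (int i = 0; i < HWo; ++i) {
        if (ib[i] < 0) continue;
        sdy += dyb[i];
        sdyx += dyb[i] * (xb[ib[i]] - mu) * is;
      }
    }
    dgamma[c] = sdyx; dbeta[c] = sdy;
    const double gis = gamma[c] * is;
    const double m1 = sdy / N, m2 = sdyx / N;
    for (int b = 0; b < B; ++b) {
      const double* xb = &X(0, b) + (std::size_t)HW * c;
      double* dxb = &dX(0, b) + (std::size_t)HW * c;
      for (int i = 0; i < HW; ++i)
        dxb[i] = gis * (-m1 - (xb[i] - mu) * is * m2);
    }
    for (int b = 0; b < B; ++b) {
      const double* dyb = &dY(0, b) + (std::size_t)HWo * c;
      const int* ib = &idx(0, b) + (std::size_t)HWo * c;
      double* dxb = &dX(0, b);
      for (int i = 0; i < HWo; ++i)
        if (ib[i] >= 0) dxb[ib[i]] += gis * dyb[i];
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Stand-alone batch norm + ReLU (kept for unit-level verification of the
// fused kernel's statistics and gradients on small inputs).
// [[Rcpp::export]]
List cpp_bnrelu_fw(NumericMatrix X, int HW, int C,
                   NumericVector gamma, NumericVector beta, double eps,
                   bool training,
                   NumericVector run_mean, NumericVector run_var) {
  const int B = X.ncol();
  const std::size_t n_in = (std::size_t)HW * C;
  NumericMatrix Y(X.nrow(), B);
  if (!training) {
    for (int c = 0; c < C; ++c) {
      const double is = 1.0 / std::sqrt(run_var[c] + eps);
      const double g = gamma[c], bt = beta[c], mu = run_mean[c];
      for (int b = 0; b < B; ++b) {
        const double* xb = &X(0, b) + (std::size_t)HW * c;
        double* yb = &Y(0, b) + (std::size_t)HW * c;
        for (int i = 0; i < HW; ++i) {
          const double v = g * (xb[i] - mu) * is + bt;
          yb[i] = v > 0.0 ? v : 0.0;
        }
      }
    }
    (void)n_in;
    return List::create(_["y"] = Y);
  }
  NumericMatrix Xhat(X.nrow(), B);
  NumericVector mean(C), var(C), invstd(C);
  const double N = (double)HW * B;
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int b = 0; b < B; ++b) {
      const double* xb = &X(0, b) + (std::size_t)HW * c;
      for (int i = 0; i < HW; ++i) { s += xb[i]; s2 += xb[i] * xb[i]; }
    }
    const double mu = s / N;
    double v = s2 / N - mu * mu;
    if (v < 0) v = 0;
    mean[c] = mu; var[c] = v;
    const double is = 1.0 / std::sqrt(v + eps);
    invstd[c] = is;
    const double g = gamma[c], bt = beta[c];
    for (int b = 0; b < B; ++b) {
      const double* xb = &X(0, b) + (std::size_t)HW * c;
      double* hb = &Xhat(0, b) + (std::size_t)HW * c;
      double* yb = &Y(0, b) + (std::size_t)HW * c;
      for (int i = 0; i < HW; ++i) {
        const double xh = (xb[i] - mu) * is;
        hb[i] = xh;
        const double val = g * xh + bt;
        yb[i] = val > 0.0 ? val : 0.0;
      }
    }
  }
  return List::create(_["y"] = Y, _["xhat"] = Xhat, _["invstd"] = invstd,
                      _["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
List cpp_bnrelu_bw(NumericMatrix dY, NumericMatrix Xhat, int HW, int C,
                   NumericVector gamma, NumericVector beta,
                   NumericVector invstd) {
  const int B = dY.ncol();
  const double N = (double)HW * B;
  NumericMatrix dX(dY.nrow(), B);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double g = gamma[c], bt = beta[c];
    double sdy = 0.0, sdyx = 0.0;
    for (int b = 0; b < B; ++b) {
      const double* dyb = &dY(0, b) + (std::size_t)HW * c;
      const double* hb = &Xhat(0, b) + (std::size_t)HW * c;
      for (int i = 0; i < HW; ++i) {
        // ReLU gate: forward output was positive iff g*xhat + beta > 0
        if (g * hb[i] + bt > 0.0) { sdy += dyb[i]; sdyx += dyb[i] * hb[i]; }
      }
    }
    dgamma[c] = sdyx; dbeta[c] = sdy;
    const double gis = g * invstd[c];
    const double m1 = sdy / N, m2 = sdyx / N;
    for (int b = 0; b < B; ++b) {
      const double* dyb = &dY(0, b) + (std::size_t)HW * c;
      const double* hb = &Xhat(0, b) + (std::size_t)HW * c;
      double* dxb = &dX(0, b) + (std::size_t)HW * c;
      for (int i = 0; i < HW; ++i) {
        const double dyr = (g * hb[i] + bt > 0.0) ? dyb[i] : 0.0;
        dxb[i] = gis * (dyr - m1 - hb[i] * m2);
      }
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericMatrix X, int H, int W, int C, int ph, int pw) {
  const int B = X.ncol();
  const int Ho = H / ph, Wo = W / pw;
  NumericMatrix Y(Ho * Wo * C, B);
  IntegerMatrix idx(Ho * Wo * C, B);
  for (int b = 0; b < B; ++b) {
    const double* xb = &X(0, b);
    double* yb = &Y(0, b);
    int* ib = &idx(0, b);
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -HUGE_VAL; int bi = -1;
          for (int dw = 0; dw < pw; ++dw)
            for (int dh = 0; dh < ph; ++dh) {
              const int h = ho * ph + dh, w = wo * pw + dw;
              const std::size_t k =
                h + (std::size_t)H * (w + (std::size_t)W * c);
              if (xb[k] > best) { best = xb[k]; bi = (int)k; }
            }
          const std::size_t o =
            ho + (std::size_t)Ho * (wo + (std::size_t)Wo * c);
          yb[o] = best; ib[o] = bi;
        }
  }
  return List::create(_["y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bw(NumericMatrix dY, IntegerMatrix idx, int n_in) {
  const int B = dY.ncol();
  NumericMatrix dX(n_in, B);
  for (int b = 0; b < B; ++b) {
    double* dxb = &dX(0, b);
    const double* dyb = &dY(0, b);
    const int* ib = &idx(0, b);
    for (int i = 0; i < dY.nrow(); ++i) dxb[ib[i]] += dyb[i];
  }
  return dX;
}

// 8-connected labeling of a binary mask (two-pass union-find).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 0;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      if (!mask(h, w)) continue;
      int lbl = 0;
      const int dh[4] = {-1, -1, -1, 0};
      const int dw[4] = {-1, 0, 1, -1};
      // neighbors already scanned in (h fastest, then w) column-major order
      const int nh[4] = {h - 1, h - 1, h + 1, h};
      const int nw[4] = {w, w - 1, w - 1, w - 1};
      (void)dh; (void)dw;
      for (int k = 0; k < 4; ++k) {
        const int hh = nh[k], ww = nw[k];
        if (hh < 0 || hh >= H || ww < 0 || ww >= W) continue;
        const int l2 = lab(hh, ww);
        if (l2 > 0) {
          if (lbl == 0) lbl = l2; else unite(lbl, l2);
        }
      }
      if (lbl == 0) { lbl = ++next; parent.push_back(lbl); }
      lab(h, w) = lbl;
    }
  // second pass: compress and renumber consecutively
  std::vector<int> remap(next + 1, 0);
  int K = 0;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      if (lab(h, w) == 0) continue;
      const int r = find(lab(h, w));
      if (remap[r] == 0) remap[r] = ++K;
      lab(h, w) = remap[r];
    }
  return lab;
}
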