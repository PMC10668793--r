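// Low-level tensor ops for the detector: dense and depthwise 2-D convolution
// (forward + backward, im2col/GEMM) and stride-1 max pooling with argmax.
// Tensor layout everywhere: column-major R array [H, W, C, N].
// Dense conv weights: [k, k, Cin, Cout]; depthwise weights: [k, k, C].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline size_t idx4(int h, int w, int c, int n, int H, int W, int C) {
  return (size_t)h + (size_t)H * ((size_t)w + (size_t)W * ((size_t)c + (size_t)C * n));
}

// fill im2col matrix M (Ho*Wo x k*k*C) for sample n; M must be zeroed by caller
static void im2col(const double* x, int n, int H, int W, int C,
                   int k, int stride, int pad, int Ho, int Wo, arma::mat& M) {
  for (int ci = 0; ci < C; ci++)
    for (int kj = 0; kj < k; kj++)
      for (int ki = 0; ki < k; ki++) {
        int col = ki + k * kj + k * k * ci;
        for (int wo = 0; wo < Wo; wo++) {
          int ws = wo * stride - pad + kj;
          if (ws < 0 || ws >= W) continue;
          for (int ho = 0; ho < Ho; ho++) {
            int hs = ho * stride - pad + ki;
            if (hs < 0 || hs >= H) continue;
            M(ho + (size_t)Ho * wo, col) = x[idx4(hs, ws, ci, n, H, W, C)];
          }
        }
      }
}

// scatter-add columns of dM back into dx for sample n (inverse of im2col)
static void col2im(const arma::mat& dM, double* dx, int n, int H, int W, int C,
                   int k, int stride, int pad, int Ho, int Wo) {
  for (int ci = 0; ci < C; ci++)
    for (int kj = 0; kj < k; kj++)
      for (int ki = 0; ki < k; ki++) {
        int col = ki + k * kj + k * k * ci;
        for (int wo = 0; wo < Wo; wo++) {
          int ws = wo * stride - pad + kj;
          if (ws < 0 || ws >= W) continue;
          for (int ho = 0; ho < Ho; ho++) {
            int hs = ho * stride - pad + ki;
            if (hs < 0 || hs >= H) continue;
            dx[idx4(hs, ws, ci, n, H, W, C)] += dM(ho + (size_t)Ho * wo, col);
          }
        }
      }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector wt, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = wt.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  if (wd[2] != C) stop("conv2d: weight Cin (%d) != input C (%d)", (int)wd[2], C);
  int Ho = (H + 2 * pad - k) / stride + 1, Wo = (W + 2 * pad - k) / stride + 1;
  arma::mat W2(const_cast<double*>(wt.begin()), (size_t)k * k * C, Cout, false, true);
  NumericVector y((size_t)Ho * Wo * Cout * N);
  size_t plane = (size_t)Ho * Wo;
  if (k == 1 && stride == 1 && pad == 0) {
    // pointwise conv: one GEMM per sample on the contiguous [HW, C] slab
    for (int n = 0; n < N; n++) {
      arma::mat Xn(const_cast<double*>(x.begin()) + plane * C * n, plane, C, false, true);
      arma::mat Yn(y.begin() + plane * Cout * n, plane, Cout, false, true);
      Yn = Xn * W2;
    }
    y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
    return y;
  }
  arma::mat M(plane, (size_t)k * k * C);
  for (int n = 0; n < N; n++) {
    M.zeros();
    im2col(x.begin(), n, H, W, C, k, stride, pad, Ho, Wo, M);
    arma::mat Y = M * W2;
    std::copy(Y.begin(), Y.end(), y.begin() + plane * Cout * n);
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector wt, NumericVector dy,
                   int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = wt.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  arma::mat W2(const_cast<double*>(wt.begin()), (size_t)k * k * C, Cout, false, true);
  NumericVector dx((size_t)H * W * C * N);
  NumericVector dw((size_t)k * k * C * Cout);
  arma::mat dW2(dw.begin(), (size_t)k * k * C, Cout, false, true);
  if (k == 1 && stride == 1 && pad == 0) {
    size_t plane = (size_t)H * W;
    for (int n = 0; n < N; n++) {
      arma::mat Xn(const_cast<double*>(x.begin()) + plane * C * n, plane, C, false, true);
      arma::mat dYn(const_cast<double*>(dy.begin()) + plane * Cout * n, plane, Cout, false, true);
      arma::mat dXn(dx.begin() + plane * C * n, plane, C, false, true);
      dW2 += Xn.t() * dYn;
      dXn = dYn * W2.t();
    }
    dx.attr("dim") = xd;
    dw.attr("dim") = wd;
    return List::create(_["dx"] = dx, _["dw"] = dw);
  }
  arma::mat M((size_t)Ho * Wo, (size_t)k * k * C);
  for (int n = 0; n < N; n++) {
    M.zeros();
    im2col(x.begin(), n, H, W, C, k, stride, pad, Ho, Wo, M);
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)Ho * Wo * Cout * n,
                 (size_t)Ho * Wo, Cout, false, true);
    dW2 += M.t() * dY;
    arma::mat dM = dY * W2.t();
    col2im(dM, dx.begin(), n, H, W, C, k, stride, pad, Ho, Wo);
  }
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// [[Rcpp::export]]
NumericVector cpp_dwconv2d_fw(NumericVector x, NumericVector wt, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = wt.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0];
  if (wd[2] != C) stop("dwconv2d: weight C (%d) != input C (%d)", (int)wd[2], C);
  int Ho = (H + 2 * pad - k) / stride + 1, Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((size_t)Ho * Wo * C * N);
  const double* px = x.begin();
  const double* pw = wt.begin();
  double* py = y.begin();
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++) {
      const double* wk = pw + (size_t)k * k * c;
      const double* xs = px + (size_t)H * W * ((size_t)c + (size_t)C * n);
      double* ys = py + (size_t)Ho * Wo * ((size_t)c + (size_t)C * n);
      for (int wo = 0; wo < Wo; wo++) {
        int wbase = wo * stride - pad;
        bool w_in = wbase >= 0 && wbase + k <= W;
        for (int ho = 0; ho < Ho; ho++) {
          int hbase = ho * stride - pad;
          double acc = 0.0;
          if (w_in && hbase >= 0 && hbase + k <= H) {
            // interior: straight pointer walk over the k x k patch
            const double* col = xs + hbase + (size_t)H * wbase;
            const double* wp = wk;
            for (int kj = 0; kj < k; kj++, col += H, wp += k)
              for (int ki = 0; ki < k; ki++) acc += wp[ki] * col[ki];
          } else {
            for (int kj = 0; kj < k; kj++) {
              int ws = wbase + kj;
              if (ws < 0 || ws >= W) continue;
              for (int ki = 0; ki < k; ki++) {
                int hs = hbase + ki;
                if (hs < 0 || hs >= H) continue;
                acc += wk[ki + k * kj] * xs[hs + (size_t)H * ws];
              }
            }
          }
          ys[ho + (size_t)Ho * wo] = acc;
        }
      }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv2d_bw(NumericVector x, NumericVector wt, NumericVector dy,
                     int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = wt.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0];
  int Ho = yd[0], Wo = yd[1];
  NumericVector dx((size_t)H * W * C * N), dw((size_t)k * k * C);
  const double* px = x.begin();
  const double* pw = wt.begin();
  const double* pdy = dy.begin();
  double* pdx = dx.begin();
  double* pdw = dw.begin();
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++) {
      const double* wk = pw + (size_t)k * k * c;
      double* dwk = pdw + (size_t)k * k * c;
      const double* xs = px + (size_t)H * W * ((size_t)c + (size_t)C * n);
      double* dxs = pdx + (size_t)H * W * ((size_t)c + (size_t)C * n);
      const double* dys = pdy + (size_t)Ho * Wo * ((size_t)c + (size_t)C * n);
      for (int wo = 0; wo < Wo; wo++) {
        int wbase = wo * stride - pad;
        bool w_in = wbase >= 0 && wbase + k <= W;
        for (int ho = 0; ho < Ho; ho++) {
          double g = dys[ho + (size_t)Ho * wo];
          if (g == 0.0) continue;
          int hbase = ho * stride - pad;
          if (w_in && hbase >= 0 && hbase + k <= H) {
            const double* col = xs + hbase + (size_t)H * wbase;
            double* dcol = dxs + hbase + (size_t)H * wbase;
            const double* wp = wk;
            double* dwp = dwk;
            for (int kj = 0; kj < k; kj++, col += H, dcol += H, wp += k, dwp += k)
              for (int ki = 0; ki < k; ki++) {
                dcol[ki] += g * wp[ki];
                dwp[ki] += g * col[ki];
              }
          } else {
            for (int kj = 0; kj < k; kj++) {
              int ws = wbase + kj;
              if (ws < 0 || ws >= W) continue;
              for (int ki = 0; ki < k; ki++) {
                int hs = hbase + ki;
                if (hs < 0 || hs >= H) continue;
                size_t xi = hs + (size_t)H * ws;
                dxs[xi] += g * wk[ki + k * kj];
                dwk[ki + k * kj] += g * xs[xi];
              }
            }
          }
        }
      }
    }
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// stride-1 max pool with same-size padding (pad = k %/% 2); argmax as 1-based
// linear index into x for exact backward routing. Padded cells never win
// because the window always contains at least one real cell.
// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, int k) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int pad = k / 2;
  NumericVector y((size_t)H * W * C * N);
  IntegerVector arg((size_t)H * W * C * N);
  const double* px = x.begin();
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++)
      for (int wo = 0; wo < W; wo++)
        for (int ho = 0; ho < H; ho++) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bi = 0;
          for (int kj = 0; kj < k; kj++) {
            int ws = wo - pad + kj;
            if (ws < 0 || ws >= W) continue;
            for (int ki = 0; ki < k; ki++) {
              int hs = ho - pad + ki;
              if (hs < 0 || hs >= H) continue;
              size_t xi = idx4(hs, ws, c, n, H, W, C);
              if (px[xi] > best) { best = px[xi]; bi = xi; }
            }
          }
          size_t yi = idx4(ho, wo, c, n, H, W, C);
          y[yi] = best;
          arg[yi] = (int)(bi + 1);
        }
  y.attr("dim") = xd;
  arg.attr("dim") = xd;
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector dy, IntegerVector argmax) {
  NumericVector dx((size_t)dy.size());
  for (R_xlen_t i = 0; i < dy.size(); i++) dx[argmax[i] - 1] += dy[i];
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

// separable stride-1 max pool (row pass then column pass), argmax kept
// exact by composing the per-pass argmax indices
// [[Rcpp::export]]
List cpp_maxpool_fw2(NumericVector x, int k) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int pad = k / 2;
  size_t plane = (size_t)H * W;
  NumericVector y(plane * C * N);
  IntegerVector arg(plane * C * N);
  std::vector<double> tmp(plane);
  std::vector<int> targ(plane);
  const double* px = x.begin();
  double* py = y.begin();
  int* parg = arg.begin();
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++) {
      const double* xs = px + plane * ((size_t)c + (size_t)C * n);
      // pass 1: max over the column (W) window for each (h, w)
      for (int h = 0; h < H; h++)
        for (int w = 0; w < W; w++) {
          double best = -std::numeric_limits<double>::infinity();
          int bw = w;
          int w0 = std::max(0, w - pad), w1 = std::min(W - 1, w + pad);
          for (int ww = w0; ww <= w1; ww++) {
            double v = xs[h + (size_t)H * ww];
            if (v > best) { best = v; bw = ww; }
          }
          tmp[h + (size_t)H * w] = best;
          targ[h + (size_t)H * w] = bw;
        }
      // pass 2: max over the row (H) window of the pass-1 result
      double* ys = py + plane * ((size_t)c + (size_t)C * n);
      int* as = parg + plane * ((size_t)c + (size_t)C * n);
      for (int w = 0; w < W; w++)
        for (int h = 0; h < H; h++) {
          double best = -std::numeric_limits<double>::infinity();
          int bh = h;
          int h0 = std::max(0, h - pad), h1 = std::min(H - 1, h + pad);
          for (int hh = h0; hh <= h1; hh++) {
            double v = tmp[hh + (size_t)H * w];
            if (v > best) { best = v; bh = hh; }
          }
          size_t yi = h + (size_t)H * w;
          ys[yi] = best;
          int srcw = targ[bh + (size_t)H * w];
          as[yi] = (int)(1 + (size_t)bh + (size_t)H * (srcw + (size_t)W * ((size_t)c + (size_t)C * n)));
        }
    }
  y.attr("dim") = xd;
  arg.attr("dim") = xd;
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_relu6_fw(NumericVector x) {
  NumericVector y(clone(x));
  for (R_xlen_t i = 0; i < y.size(); i++) {
    if (y[i] < 0) y[i] = 0; else if (y[i] > 6) y[i] = 6;
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu6_bw(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  for (R_xlen_t i = 0; i < dy.size(); i++) {
    dx[i] = (y[i] > 0 && y[i] < 6) ? dy[i] : 0.0;
  }
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

// per-channel mean/var over (H, W, N) of an [H,W,C,N] array
// [[Rcpp::export]]
List cpp_bn_stats(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t plane = (size_t)H * W;
  NumericVector mu(C), va(C);
  const double* px = x.begin();
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++) {
      const double* xs = px + plane * ((size_t)c + (size_t)C * n);
      double s = 0;
      for (size_t i = 0; i < plane; i++) s += xs[i];
      mu[c] += s;
    }
  double denom = (double)plane * N;
  for (int c = 0; c < C; c++) mu[c] /= denom;
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++) {
      const double* xs = px + plane * ((size_t)c + (size_t)C * n);
      double s = 0, m = mu[c];
      for (size_t i = 0; i < plane; i++) { double d = xs[i] - m; s += d * d; }
      va[c] += s;
    }
  for (int c = 0; c < C; c++) va[c] /= denom;
  return List::create(_["mean"] = mu, _["var"] = va, _["n"] = denom);
}

// y = (x - mean[c]) * istd[c] * gamma[c] + beta[c], optionally fused with
// ReLU6 clamping; also returns the normalized xhat for the backward pass
// [[Rcpp::export]]
List cpp_bn_fw(NumericVector x, NumericVector mu, NumericVector istd,
               NumericVector gamma, NumericVector beta, bool relu6 = false) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t plane = (size_t)H * W;
  NumericVector y(x.size()), xhat(x.size());
  const double* px = x.begin();
  double* py = y.begin();
  double* ph = xhat.begin();
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++) {
      size_t off = plane * ((size_t)c + (size_t)C * n);
      double m = mu[c], is = istd[c], g = gamma[c], b = beta[c];
      for (size_t i = 0; i < plane; i++) {
        double h = (px[off + i] - m) * is;
        ph[off + i] = h;
        double v = h * g + b;
        if (relu6) { if (v < 0) v = 0; else if (v > 6) v = 6; }
        py[off + i] = v;
      }
    }
  y.attr("dim") = xd;
  xhat.attr("dim") = xd;
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// batch-norm backward (training mode); when the forward fused ReLU6, the
// saturated positions (y == 0 or y == 6) are masked out of dy first.
// Returns dx, dgamma, dbeta.
// [[Rcpp::export]]
List cpp_bn_bw(NumericVector dy, NumericVector xhat, NumericVector istd,
               NumericVector gamma, bool train,
               Nullable<NumericVector> y_relu = R_NilValue) {
  IntegerVector xd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t plane = (size_t)H * W;
  NumericVector dg(C), db(C), dx(dy.size());
  const double* pdy = dy.begin();
  const double* ph = xhat.begin();
  const double* pyr = NULL;
  if (y_relu.isNotNull()) pyr = NumericVector(y_relu).begin();
  double* pdx = dx.begin();
  // pass 1: masked per-channel sums; stash masked dy in dx temporarily
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++) {
      size_t off = plane * ((size_t)c + (size_t)C * n);
      double sg = 0, sb = 0;
      for (size_t i = 0; i < plane; i++) {
        double d = pdy[off + i];
        if (pyr && (pyr[off + i] <= 0.0 || pyr[off + i] >= 6.0)) d = 0.0;
        pdx[off + i] = d;
        sg += d * ph[off + i];
        sb += d;
      }
      dg[c] += sg;
      db[c] += sb;
    }
  double nn = (double)plane * N;
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++) {
      size_t off = plane * ((size_t)c + (size_t)C * n);
      double g = gamma[c], is = istd[c];
      double s1 = db[c] / nn, s2 = dg[c] / nn;
      for (size_t i = 0; i < plane; i++) {
        double dxh = pdx[off + i] * g;
        if (train) {
          pdx[off + i] = (dxh - g * s1 - ph[off + i] * g * s2) * is;
        } else {
          pdx[off + i] = dxh * is;
        }
      }
    }
  dx.attr("dim") = xd;
  return List::create(_["dx"] = dx, _["dgamma"] = dg, _["dbeta"] = db);
}

// max and mean over dim 3 (channels) of [H,W,C,N]; argmax 1-based channel
// [[Rcpp::export]]
List cpp_reduce3(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t plane = (size_t)H * W;
  NumericVector mx(plane * N), mn(plane * N);
  IntegerVector idx(plane * N);
  const double* px = x.begin();
  for (int n = 0; n < N; n++) {
    size_t oo = plane * n;
    for (size_t i = 0; i < plane; i++) {
      double best = px[i + plane * (size_t)C * n];
      int bc = 1;
      double s = 0;
      for (int c = 0; c < C; c++) {
        double v = px[i + plane * ((size_t)c + (size_t)C * n)];
        s += v;
        if (v > best) { best = v; bc = c + 1; }
      }
      mx[oo + i] = best;
      mn[oo + i] = s / C;
      idx[oo + i] = bc;
    }
  }
  IntegerVector od = IntegerVector::create(H, W, 1, N);
  mx.attr("dim") = od;
  mn.attr("dim") = od;
  idx.attr("dim") = od;
  return List::create(_["max"] = mx, _["mean"] = mn, _["idx"] = idx);
}

// y = x * g broadcast over channels (g is [H,W,1,N])
// [[Rcpp::export]]
NumericVector cpp_bcast_mul(NumericVector x, NumericVector g) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t plane = (size_t)H * W;
  NumericVector y(x.size());
  const double* px = x.begin();
  const double* pg = g.begin();
  double* py = y.begin();
  for (int n = 0; n < N; n++) {
    const double* gs = pg + plane * n;
    for (int c = 0; c < C; c++) {
      size_t off = plane * ((size_t)c + (size_t)C * n);
      for (size_t i = 0; i < plane; i++) py[off + i] = px[off + i] * gs[i];
    }
  }
  y.attr("dim") = xd;
  return y;
}

// backward of the gated multiply + pooled branch:
// dx = dy*g (broadcast) + route(dmx to argmax channel) + dmn/C; also dg
// [[Rcpp::export]]
List cpp_gate_bw(NumericVector dy, NumericVector x, NumericVector g,
                 IntegerVector idx, NumericVector dmx, NumericVector dmn) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t plane = (size_t)H * W;
  NumericVector dx(x.size());
  NumericVector dg(plane * N);
  const double* pdy = dy.begin();
  const double* px = x.begin();
  const double* pg = g.begin();
  const int* pidx = idx.begin();
  const double* pdmx = dmx.begin();
  const double* pdmn = dmn.begin();
  double* pdx = dx.begin();
  double* pdg = dg.begin();
  for (int n = 0; n < N; n++) {
    const double* gs = pg + plane * n;
    const double* dmxs = pdmx + plane * n;
    const double* dmns = pdmn + plane * n;
    const int* idxs = pidx + plane * n;
    double* dgs = pdg + plane * n;
    for (int c = 0; c < C; c++) {
      size_t off = plane * ((size_t)c + (size_t)C * n);
      for (size_t i = 0; i < plane; i++) {
        double d = pdy[off + i];
        pdx[off + i] = d * gs[i] + dmns[i] / C + (idxs[i] == c + 1 ? dmxs[i] : 0.0);
        dgs[i] += d * px[off + i];
      }
    }
  }
  dx.attr("dim") = xd;
  dg.attr("dim") = IntegerVector::create(H, W, 1, N);
  return List::create(_["dx"] = dx, _["dg"] = dg);
}

// gradient of the gate for a gated multiply: dg[h,w,n] = sum_c dy*x
// [[Rcpp::export]]
NumericVector cpp_gate_dg(NumericVector dy, NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t plane = (size_t)H * W;
  NumericVector dg(plane * N);
  const double* pdy = dy.begin();
  const double* px = x.begin();
  double* pdg = dg.begin();
  for (int n = 0; n < N; n++) {
    double* dgs = pdg + plane * n;
    for (int c = 0; c < C; c++) {
      size_t off = plane * ((size_t)c + (size_t)C * n);
      for (size_t i = 0; i < plane; i++) dgs[i] += pdy[off + i] * px[off + i];
    }
  }
  dg.attr("dim") = IntegerVector::create(H, W, 1, N);
  return dg;
}
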