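// Low-level dense kernels for feature-map operations.
//
// Feature maps are R arrays with dim (H, W, C, N); column-major, so a single
// channel plane is contiguous with the row index fastest.  Convolution weights
// are arrays with dim (kh, kw, in_per_group, out), which viewed column-major is
// exactly the (kh*kw*in_per_group) x out matrix the im2col product needs.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline void get4(const NumericVector& x, int* d) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// im2col for one (sample, group) slab.
// xs points at x(0,0,c0,n); fills M (kh*kw*cin_g rows, Hout*Wout cols).
static void im2col(const double* xs, int H, int W, int cin_g,
                   int kh, int kw, int stride, int pad,
                   int Hout, int Wout, arma::mat& M) {
  const int HW = H * W;
  for (int ow = 0; ow < Wout; ++ow) {
    for (int oh = 0; oh < Hout; ++oh) {
      const int p = oh + Hout * ow;
      double* col = M.colptr(p);
      const int h0 = oh * stride - pad;
      const int w0 = ow * stride - pad;
      for (int ci = 0; ci < cin_g; ++ci) {
        const double* plane = xs + (size_t)HW * ci;
        for (int j = 0; j < kw; ++j) {
          const int wI = w0 + j;
          const bool wok = (wI >= 0 && wI < W);
          for (int i = 0; i < kh; ++i) {
            const int hI = h0 + i;
            const int r = i + kh * (j + kw * ci);
            col[r] = (wok && hI >= 0 && hI < H) ? plane[hI + H * wI] : 0.0;
          }
        }
      }
    }
  }
}

// scatter-add transpose of im2col
static void col2im(const arma::mat& M, double* xs, int H, int W, int cin_g,
                   int kh, int kw, int stride, int pad,
                   int Hout, int Wout) {
  const int HW = H * W;
  for (int ow = 0; ow < Wout; ++ow) {
    for (int oh = 0; oh < Hout; ++oh) {
      const int p = oh + Hout * ow;
      const double* col = M.colptr(p);
      const int h0 = oh * stride - pad;
      const int w0 = ow * stride - pad;
      for (int ci = 0; ci < cin_g; ++ci) {
        double* plane = xs + (size_t)HW * ci;
        for (int j = 0; j < kw; ++j) {
          const int wI = w0 + j;
          if (wI < 0 || wI >= W) continue;
          for (int i = 0; i < kh; ++i) {
            const int hI = h0 + i;
            if (hI < 0 || hI >= H) continue;
            plane[hI + H * wI] += col[i + kh * (j + kw * ci)];
          }
        }
      }
    }
  }
}

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w,
                         int stride, int pad, int groups) {
  int xd[4], wd[4];
  get4(x, xd); get4(w, wd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], cin_g = wd[2], Cout = wd[3];
  if (C != cin_g * groups) stop("input channels inconsistent with weight/groups");
  if (Cout % groups != 0) stop("out channels not divisible by groups");
  const int outg = Cout / groups;
  const int Hout = out_size(H, kh, stride, pad);
  const int Wout = out_size(W, kw, stride, pad);
  if (Hout < 1 || Wout < 1) stop("invalid-input: spatial dims too small for kernel");
  const int K = kh * kw * cin_g, P = Hout * Wout;

  NumericVector y(static_cast<R_xlen_t>(P) * Cout * N);
  y.attr("dim") = IntegerVector::create(Hout, Wout, Cout, N);
  arma::mat M(K, P);
  const arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);

  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      const double* xs = x.begin() + (size_t)H * W * (g * cin_g + (size_t)C * n);
      im2col(xs, H, W, cin_g, kh, kw, stride, pad, Hout, Wout, M);
      arma::mat Yt = M.t() * Wm.cols(g * outg, (g + 1) * outg - 1); // P x outg
      double* ys = y.begin() + (size_t)P * (g * outg + (size_t)Cout * n);
      std::memcpy(ys, Yt.memptr(), sizeof(double) * (size_t)P * outg);
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_bwd_x(NumericVector gy, NumericVector w,
                               IntegerVector xdim, int stride, int pad, int groups) {
  int gd[4], wd[4];
  get4(gy, gd); get4(w, wd);
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wd[0], kw = wd[1], cin_g = wd[2], Cout = wd[3];
  const int outg = Cout / groups;
  const int Hout = gd[0], Wout = gd[1];
  const int K = kh * kw * cin_g, P = Hout * Wout;

  NumericVector gx(static_cast<R_xlen_t>(H) * W * C * N);
  gx.attr("dim") = xdim;
  const arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);

  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      const arma::mat Gy(const_cast<double*>(gy.begin()) +
                             (size_t)P * (g * outg + (size_t)Cout * n),
                         P, outg, false, true);
      arma::mat M = Wm.cols(g * outg, (g + 1) * outg - 1) * Gy.t(); // K x P
      double* xs = gx.begin() + (size_t)H * W * (g * cin_g + (size_t)C * n);
      col2im(M, xs, H, W, cin_g, kh, kw, stride, pad, Hout, Wout);
    }
  }
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_bwd_w(NumericVector gy, NumericVector x,
                               IntegerVector wdim, int stride, int pad, int groups) {
  int gd[4], xd[4];
  get4(gy, gd); get4(x, xd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wdim[0], kw = wdim[1], cin_g = wdim[2], Cout = wdim[3];
  const int outg = Cout / groups;
  const int Hout = gd[0], Wout = gd[1];
  const int K = kh * kw * cin_g, P = Hout * Wout;

  NumericVector gw(static_cast<R_xlen_t>(K) * Cout);
  gw.attr("dim") = wdim;
  arma::mat Gw(gw.begin(), K, Cout, false, true);
  arma::mat M(K, P);

  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      const double* xs = x.begin() + (size_t)H * W * (g * cin_g + (size_t)C * n);
      im2col(xs, H, W, cin_g, kh, kw, stride, pad, Hout, Wout, M);
      const arma::mat Gy(const_cast<double*>(gy.begin()) +
                             (size_t)P * (g * outg + (size_t)Cout * n),
                         P, outg, false, true);
      Gw.cols(g * outg, (g + 1) * outg - 1) += M * Gy;
    }
  }
  return gw;
}

// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int k, int stride, int pad, bool ceil_mode) {
  int xd[4];
  get4(x, xd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Hout, Wout;
  if (ceil_mode) {
    Hout = (H + 2 * pad - k + stride - 1) / stride + 1;
    Wout = (W + 2 * pad - k + stride - 1) / stride + 1;
    // torch convention: last window must start inside the (padded) input
    if ((Hout - 1) * stride >= H + pad) --Hout;
    if ((Wout - 1) * stride >= W + pad) --Wout;
  } else {
    Hout = out_size(H, k, stride, pad);
    Wout = out_size(W, k, stride, pad);
  }
  NumericVector y(static_cast<R_xlen_t>(Hout) * Wout * C * N);
  y.attr("dim") = IntegerVector::create(Hout, Wout, C, N);
  IntegerVector idx(y.size()); // linear index into x of the arg-max
  const size_t HW = (size_t)H * W;

  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* plane = x.begin() + HW * (c + (size_t)C * n);
      const size_t base = HW * (c + (size_t)C * n);
      for (int ow = 0; ow < Wout; ++ow)
        for (int oh = 0; oh < Hout; ++oh) {
          double best = -std::numeric_limits<double>::infinity();
          int bestix = -1;
          const int h0 = oh * stride - pad, w0 = ow * stride - pad;
          for (int j = 0; j < k; ++j) {
            const int wI = w0 + j;
            if (wI < 0 || wI >= W) continue;
            for (int i = 0; i < k; ++i) {
              const int hI = h0 + i;
              if (hI < 0 || hI >= H) continue;
              const double v = plane[hI + H * wI];
              if (v > best) { best = v; bestix = hI + H * wI; }
            }
          }
          // output written in (oh fastest) order per plane
          const size_t oo = (size_t)(oh + Hout * ow) + (size_t)Hout * Wout * (c + (size_t)C * n);
          y[oo] = best;
          idx[oo] = bestix < 0 ? -1 : (int)(base + bestix);
          (void)o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  NumericVector gx(static_cast<R_xlen_t>(xdim[0]) * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i)
    if (idx[i] >= 0) gx[idx[i]] += gy[i];
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2(NumericVector x) {
  int xd[4];
  get4(x, xd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int H2 = 2 * H, W2 = 2 * W;
  NumericVector y(static_cast<R_xlen_t>(H2) * W2 * C * N);
  y.attr("dim") = IntegerVector::create(H2, W2, C, N);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* p = x.begin() + (size_t)H * W * cn;
    double* q = y.begin() + (size_t)H2 * W2 * cn;
    for (int w = 0; w < W2; ++w)
      for (int h = 0; h < H2; ++h)
        q[h + H2 * w] = p[(h / 2) + H * (w / 2)];
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector gy) {
  int gd[4];
  get4(gy, gd);
  const int H2 = gd[0], W2 = gd[1], C = gd[2], N = gd[3];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* q = gy.begin() + (size_t)H2 * W2 * cn;
    double* p = gx.begin() + (size_t)H * W * cn;
    for (int w = 0; w < W2; ++w)
      for (int h = 0; h < H2; ++h)
        p[(h / 2) + H * (w / 2)] += q[h + H2 * w];
  }
  return gx;
}

// bilinear resize, half-pixel centres (align_corners = FALSE)
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, int Hout, int Wout) {
  int xd[4];
  get4(x, xd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y(static_cast<R_xlen_t>(Hout) * Wout * C * N);
  y.attr("dim") = IntegerVector::create(Hout, Wout, C, N);
  const double sh = (double)H / Hout, sw = (double)W / Wout;
  std::vector<int> h0(Hout), h1(Hout), w0(Wout), w1(Wout);
  std::vector<double> fh(Hout), fw(Wout);
  for (int oh = 0; oh < Hout; ++oh) {
    double src = std::max(0.0, (oh + 0.5) * sh - 0.5);
    h0[oh] = std::min((int)src, H - 1);
    h1[oh] = std::min(h0[oh] + 1, H - 1);
    fh[oh] = src - h0[oh];
  }
  for (int ow = 0; ow < Wout; ++ow) {
    double src = std::max(0.0, (ow + 0.5) * sw - 0.5);
    w0[ow] = std::min((int)src, W - 1);
    w1[ow] = std::min(w0[ow] + 1, W - 1);
    fw[ow] = src - w0[ow];
  }
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* p = x.begin() + (size_t)H * W * cn;
    double* q = y.begin() + (size_t)Hout * Wout * cn;
    for (int ow = 0; ow < Wout; ++ow)
      for (int oh = 0; oh < Hout; ++oh) {
        const double a = fh[oh], b = fw[ow];
        q[oh + Hout * ow] =
          (1 - a) * (1 - b) * p[h0[oh] + H * w0[ow]] +
          a * (1 - b) * p[h1[oh] + H * w0[ow]] +
          (1 - a) * b * p[h0[oh] + H * w1[ow]] +
          a * b * p[h1[oh] + H * w1[ow]];
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_bwd(NumericVector gy, IntegerVector xdim) {
  int gd[4];
  get4(gy, gd);
  const int Hout = gd[0], Wout = gd[1];
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C * N);
  gx.attr("dim") = xdim;
  const double sh = (double)H / Hout, sw = (double)W / Wout;
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* q = gy.begin() + (size_t)Hout * Wout * cn;
    double* p = gx.begin() + (size_t)H * W * cn;
    for (int ow = 0; ow < Wout; ++ow) {
      double srcw = std::max(0.0, (ow + 0.5) * sw - 0.5);
      int w0 = std::min((int)srcw, W - 1), w1 = std::min(w0 + 1, W - 1);
      double b = srcw - w0;
      for (int oh = 0; oh < Hout; ++oh) {
        double srch = std::max(0.0, (oh + 0.5) * sh - 0.5);
        int h0 = std::min((int)srch, H - 1), h1 = std::min(h0 + 1, H - 1);
        double a = srch - h0;
        const double g = q[oh + Hout * ow];
        p[h0 + H * w0] += (1 - a) * (1 - b) * g;
        p[h1 + H * w0] += a * (1 - b) * g;
        p[h0 + H * w1] += (1 - a) * b * g;
        p[h1 + H * w1] += a * b * g;
      }
    }
  }
  return gx;
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Spatial attention over a level-stacked pyramid (single sample).
// F: (H, W, C, L); base, off: K x 2 (dy, dx); dm: K; wlk: L x K.
// out(h,w,c) = (1/L) sum_l sum_k wlk(l,k) * dm(k) *
//              bilinear(F_l, h + base_y+off_y, w + base_x+off_x, c)
// Sample coordinates are clamped to the feature bounds.
// [[Rcpp::export]]
NumericVector cpp_spatial_att(NumericVector F, NumericMatrix base,
                              NumericMatrix off, NumericVector dm,
                              NumericMatrix wlk) {
  int fd[4];
  get4(F, fd);
  const int H = fd[0], W = fd[1], C = fd[2], L = fd[3];
  const int K = base.nrow();
  NumericVector out(static_cast<R_xlen_t>(H) * W * C);
  out.attr("dim") = IntegerVector::create(H, W, C);
  for (int l = 0; l < L; ++l) {
    const double* Fl = F.begin() + (size_t)H * W * C * l;
    for (int k = 0; k < K; ++k) {
      const double coef = wlk(l, k) * dm[k] / L;
      if (coef == 0.0) continue;
      const double dy = base(k, 0) + off(k, 0), dx = base(k, 1) + off(k, 1);
      for (int w = 0; w < W; ++w) {
        const double sx = clampd(w + dx, 0, W - 1);
        const int x0 = std::min((int)sx, W - 1), x1 = std::min(x0 + 1, W - 1);
        const double fx = sx - x0;
        for (int h = 0; h < H; ++h) {
          const double sy = clampd(h + dy, 0, H - 1);
          const int y0 = std::min((int)sy, H - 1), y1 = std::min(y0 + 1, H - 1);
          const double fy = sy - y0;
          for (int c = 0; c < C; ++c) {
            const double* pl = Fl + (size_t)H * W * c;
            const double v =
              (1 - fy) * (1 - fx) * pl[y0 + H * x0] + fy * (1 - fx) * pl[y1 + H * x0] +
              (1 - fy) * fx * pl[y0 + H * x1] + fy * fx * pl[y1 + H * x1];
            out[(size_t)(h + H * w) + (size_t)H * W * c] += coef * v;
          }
        }
      }
    }
  }
  return out;
}

// Backward of cpp_spatial_att. gout: (H,W,C). Returns grads for F, off, dm, wlk.
// [[Rcpp::export]]
List cpp_spatial_att_bwd(NumericVector F, NumericMatrix base, NumericMatrix off,
                         NumericVector dm, NumericMatrix wlk, NumericVector gout) {
  int fd[4];
  get4(F, fd);
  const int H = fd[0], W = fd[1], C = fd[2], L = fd[3];
  const int K = base.nrow();
  NumericVector gF(F.size());
  gF.attr("dim") = F.attr("dim");
  NumericMatrix goff(K, 2);
  NumericVector gdm(K);
  NumericMatrix gwlk(L, K);

  for (int l = 0; l < L; ++l) {
    const double* Fl = F.begin() + (size_t)H * W * C * l;
    double* gFl = gF.begin() + (size_t)H * W * C * l;
    for (int k = 0; k < K; ++k) {
      const double wv = wlk(l, k), mv = dm[k];
      const double coef = wv * mv / L;
      const double dy = base(k, 0) + off(k, 0), dx = base(k, 1) + off(k, 1);
      double acc_w = 0, acc_y = 0, acc_x = 0;
      for (int w = 0; w < W; ++w) {
        const double rx = w + dx;
        const double sx = clampd(rx, 0, W - 1);
        const bool xin = (rx > 0 && rx < W - 1);
        const int x0 = std::min((int)sx, W - 1), x1 = std::min(x0 + 1, W - 1);
        const double fx = sx - x0;
        for (int h = 0; h < H; ++h) {
          const double ry = h + dy;
          const double sy = clampd(ry, 0, H - 1);
          const bool yin = (ry > 0 && ry < H - 1);
          const int y0 = std::min((int)sy, H - 1), y1 = std::min(y0 + 1, H - 1);
          const double fy = sy - y0;
          for (int c = 0; c < C; ++c) {
            const double g = gout[(size_t)(h + H * w) + (size_t)H * W * c];
            if (g == 0.0) continue;
            const double* pl = Fl + (size_t)H * W * c;
            const double v00 = pl[y0 + H * x0], v10 = pl[y1 + H * x0];
            const double v01 = pl[y0 + H * x1], v11 = pl[y1 + H * x1];
            const double v = (1 - fy) * (1 - fx) * v00 + fy * (1 - fx) * v10 +
                             (1 - fy) * fx * v01 + fy * fx * v11;
            acc_w += g * v;
            double* gpl = gFl + (size_t)H * W * c;
            const double gc = g * coef;
            gpl[y0 + H * x0] += gc * (1 - fy) * (1 - fx);
            gpl[y1 + H * x0] += gc * fy * (1 - fx);
            gpl[y0 + H * x1] += gc * (1 - fy) * fx;
            gpl[y1 + H * x1] += gc * fy * fx;
            if (yin) acc_y += g * ((1 - fx) * (v10 - v00) + fx * (v11 - v01));
            if (xin) acc_x += g * ((1 - fy) * (v01 - v00) + fy * (v11 - v10));
          }
        }
      }
      gwlk(l, k) += acc_w * mv / L;
      gdm[k] += acc_w * wv / L;
      goff(k, 0) += acc_y * coef;
      goff(k, 1) += acc_x * coef;
    }
  }
  return List::create(_["gF"] = gF, _["goff"] = goff, _["gdm"] = gdm,
                      _["gwlk"] = gwlk);
}
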