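// Low-level numeric kernels: same-size stride-1 2-D convolution via
// im2col + GEMM, 2x2 max pooling, bilinear x2 upsampling, and an exact
// Euclidean distance transform.  Arrays use R's column-major layout
// (H, W, C, N): row index fastest.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat weight_matrix(const NumericVector& w,
                                      int kh, int kw, int cin, int cout) {
  // rows: output kernel, cols: (ki, kj, c) with ki fastest
  arma::mat W(cout, kh * kw * cin);
  for (int co = 0; co < cout; ++co)
    for (int c = 0; c < cin; ++c)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          W(co, ki + kh * (kj + kw * c)) =
            w[ki + kh * (kj + kw * (c + cin * co))];
  return W;
}

static void im2col(const double* x, int H, int W, int cin,
                   int kh, int kw, int pad, arma::mat& cols) {
  // cols: (kh*kw*cin) x (H*W)
  for (int c = 0; c < cin; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int row = ki + kh * (kj + kw * c);
        for (int ow = 0; ow < W; ++ow) {
          int iw = ow + kj - pad;
          double* dst = cols.memptr() + (size_t)cols.n_rows * (size_t)H * ow + row;
          if (iw < 0 || iw >= W) {
            for (int oh = 0; oh < H; ++oh)
              dst[(size_t)cols.n_rows * oh] = 0.0;
          } else {
            const double* src = xc + (size_t)H * iw;
            for (int oh = 0; oh < H; ++oh) {
              int ih = oh + ki - pad;
              dst[(size_t)cols.n_rows * oh] =
                (ih < 0 || ih >= H) ? 0.0 : src[ih];
            }
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& cols, int H, int W, int cin,
                       int kh, int kw, int pad, double* gx) {
  for (int c = 0; c < cin; ++c) {
    double* gc = gx + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int row = ki + kh * (kj + kw * c);
        for (int ow = 0; ow < W; ++ow) {
          int iw = ow + kj - pad;
          if (iw < 0 || iw >= W) continue;
          const double* src = cols.memptr() + (size_t)cols.n_rows * (size_t)H * ow + row;
          double* dst = gc + (size_t)H * iw;
          for (int oh = 0; oh < H; ++oh) {
            int ih = oh + ki - pad;
            if (ih >= 0 && ih < H)
              dst[ih] += src[(size_t)cols.n_rows * oh];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                        int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], cout = wd[3];
  arma::mat Wm = weight_matrix(w, kh, kw, cin, cout);
  NumericVector y((size_t)H * W * cout * N);
  y.attr("dim") = IntegerVector::create(H, W, cout, N);
  size_t hw = (size_t)H * W;
  if (kh == 1 && kw == 1) {
    // pointwise: per image y = x (HW x cin) * W^t + bias
    for (int n = 0; n < N; ++n) {
      arma::mat Xv(x.begin() + hw * cin * n, hw, cin, false, true);
      arma::mat Yv(y.begin() + hw * cout * n, hw, cout, false, true);
      Yv = Xv * Wm.t();
      for (int co = 0; co < cout; ++co) Yv.col(co) += b[co];
    }
    return y;
  }
  arma::mat cols(kh * kw * cin, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * cin * n, H, W, cin, kh, kw, pad, cols);
    arma::mat ym = Wm * cols;  // cout x (H*W)
    double* yp = y.begin() + (size_t)H * W * cout * n;
    for (int co = 0; co < cout; ++co) {
      double bias = b[co];
      double* ypc = yp + (size_t)H * W * co;
      for (size_t q = 0; q < (size_t)H * W; ++q)
        ypc[q] = ym(co, q) + bias;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector gy, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], cout = wd[3];
  arma::mat Wm = weight_matrix(w, kh, kw, cin, cout);
  NumericVector gx((size_t)H * W * cin * N), gw(w.size()), gb(cout);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  size_t hw = (size_t)H * W;
  if (kh == 1 && kw == 1) {
    arma::mat gWm(cout, cin, arma::fill::zeros);
    for (int n = 0; n < N; ++n) {
      arma::mat Xv(x.begin() + hw * cin * n, hw, cin, false, true);
      arma::mat Gv(const_cast<double*>(gy.begin()) + hw * cout * n,
                   hw, cout, false, true);
      arma::mat GXv(gx.begin() + hw * cin * n, hw, cin, false, true);
      gWm += Gv.t() * Xv;
      GXv = Gv * Wm;
      for (int co = 0; co < cout; ++co) gb[co] += arma::accu(Gv.col(co));
    }
    for (int co = 0; co < cout; ++co)
      for (int c = 0; c < cin; ++c)
        gw[c + cin * co] = gWm(co, c);
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }
  arma::mat cols(kh * kw * cin, (size_t)H * W);
  arma::mat gWm(cout, kh * kw * cin, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * cin * n, H, W, cin, kh, kw, pad, cols);
    arma::mat gym(cout, (size_t)H * W);
    const double* gp = gy.begin() + (size_t)H * W * cout * n;
    for (int co = 0; co < cout; ++co) {
      const double* gpc = gp + (size_t)H * W * co;
      double s = 0.0;
      for (size_t q = 0; q < (size_t)H * W; ++q) {
        gym(co, q) = gpc[q];
        s += gpc[q];
      }
      gb[co] += s;
    }
    gWm += gym * cols.t();
    arma::mat gcols = Wm.t() * gym;
    col2im_add(gcols, H, W, cin, kh, kw, pad,
               gx.begin() + (size_t)H * W * cin * n);
  }
  for (int co = 0; co < cout; ++co)
    for (int c = 0; c < cin; ++c)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          gw[ki + kh * (kj + kw * (c + cin * co))] =
            gWm(co, ki + kh * (kj + kw * c));
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = ".maxpool2_fw")]]
List maxpool2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);  // 0-based flat index into x
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          // column-major over (oh, ow) but we fill y in its own layout
          size_t yq = (size_t)Ho * Wo * (c + (size_t)C * n) + oh + (size_t)Ho * ow;
          double best = -1e300; size_t bi = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              size_t q = (size_t)(2 * oh + di) + (size_t)H * (2 * ow + dj);
              double v = xc[q];
              if (v > best) { best = v; bi = q; }
            }
          y[yq] = best;
          idx[yq] = (int)(base + bi);
        }
      o += (size_t)Ho * Wo;
    }
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bw")]]
NumericVector maxpool2_bw(NumericVector gy, IntegerVector idx,
                          IntegerVector xdim) {
  size_t len = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(len);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i)
    gx[idx[i]] += gy[i];
  return gx;
}

static void up2_axis(int n_in, std::vector<int>& i0, std::vector<int>& i1,
                     std::vector<double>& t) {
  int n_out = 2 * n_in;
  i0.resize(n_out); i1.resize(n_out); t.resize(n_out);
  for (int i = 0; i < n_out; ++i) {
    double s = (i + 0.5) / 2.0 - 0.5;
    int a = (int)std::floor(s);
    double f = s - a;
    if (a < 0) { a = 0; f = 0.0; }
    if (a >= n_in - 1) { a = n_in - 1; f = 0.0; }
    i0[i] = a; i1[i] = std::min(a + 1, n_in - 1); t[i] = f;
  }
}

// [[Rcpp::export(name = ".upsample2_fw")]]
NumericVector upsample2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> r0, r1, c0, c1; std::vector<double> tr, tc;
  up2_axis(H, r0, r1, tr); up2_axis(W, c0, c1, tc);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int ow = 0; ow < Wo; ++ow) {
        const double* xl = xc + (size_t)H * c0[ow];
        const double* xr = xc + (size_t)H * c1[ow];
        double u = tc[ow];
        double* ycol = yc + (size_t)Ho * ow;
        for (int oh = 0; oh < Ho; ++oh) {
          double v = tr[oh];
          double top = (1 - u) * xl[r0[oh]] + u * xr[r0[oh]];
          double bot = (1 - u) * xl[r1[oh]] + u * xr[r1[oh]];
          ycol[oh] = (1 - v) * top + v * bot;
        }
      }
    }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bw")]]
NumericVector upsample2_bw(NumericVector gy, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> r0, r1, c0, c1; std::vector<double> tr, tc;
  up2_axis(H, r0, r1, tr); up2_axis(W, c0, c1, tc);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xdim;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* gc = gx.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* gyc = gy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int ow = 0; ow < Wo; ++ow) {
        double u = tc[ow];
        const double* gcol = gyc + (size_t)Ho * ow;
        double* gl = gc + (size_t)H * c0[ow];
        double* gr = gc + (size_t)H * c1[ow];
        for (int oh = 0; oh < Ho; ++oh) {
          double v = tr[oh], g = gcol[oh];
          gl[r0[oh]] += (1 - v) * (1 - u) * g;
          gr[r0[oh]] += (1 - v) * u * g;
          gl[r1[oh]] += v * (1 - u) * g;
          gr[r1[oh]] += v * u * g;
        }
      }
    }
  return gx;
}

// Uses a large-but-finite INF (1e20) so parabola intersections stay finite.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -1e300; z[1] = 1e300;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = 1e300;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance (in pixels) from every pixel to the nearest
// "site" pixel (sites: logical/0-1 matrix).  All-zero input -> Inf.
// [[Rcpp::export(name = ".edt")]]
NumericMatrix edt(NumericMatrix sites) {
  int H = sites.nrow(), W = sites.ncol();
  const double INF = 1e20;
  NumericMatrix d2(H, W);
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  // columns first
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) f[i] = sites(i, j) > 0 ? 0.0 : INF;
    dt1d(f, d, H);
    for (int i = 0; i < H; ++i) d2(i, j) = d[i];
  }
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) f[j] = d2(i, j);
    dt1d(f, d, W);
    for (int j = 0; j < W; ++j) d2(i, j) = d[j];
  }
  NumericMatrix out(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j)
      out(i, j) = d2(i, j) >= 1e18 ? R_PosInf : std::sqrt(d2(i, j));
  return out;
}

// ---- fused per-channel helpers --------------------------------------

// y = x * a[c] + b[c]  (a, b length C)
// [[Rcpp::export(name = ".chan_affine")]]
NumericVector chan_affine(NumericVector x, NumericVector a, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  size_t hw = (size_t)H * W;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + hw * (c + (size_t)C * n);
      double* yp = y.begin() + hw * (c + (size_t)C * n);
      double ac = a[c], bc = b[c];
      for (size_t q = 0; q < hw; ++q) yp[q] = xp[q] * ac + bc;
    }
  return y;
}

// per-channel mean and mean of squares over (H, W, N)
// [[Rcpp::export(name = ".chan_stats")]]
List chan_stats(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector mu(C), m2(C);
  size_t hw = (size_t)H * W;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + hw * (c + (size_t)C * n);
      double s = 0, s2 = 0;
      for (size_t q = 0; q < hw; ++q) { s += xp[q]; s2 += xp[q] * xp[q]; }
      mu[c] += s; m2[c] += s2;
    }
  double m = (double)hw * N;
  for (int c = 0; c < C; ++c) { mu[c] /= m; m2[c] /= m; }
  return List::create(_["mean"] = mu, _["meansq"] = m2);
}

// training-mode batchnorm backward: returns dx, dgamma, dbeta
// [[Rcpp::export(name = ".bn_bw")]]
List bn_bw(NumericVector xhat, NumericVector g, NumericVector gamma,
           NumericVector istd, bool training) {
  IntegerVector xd = xhat.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t hw = (size_t)H * W;
  double m = (double)hw * N;
  NumericVector dgamma(C), dbeta(C), dx(xhat.size());
  dx.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = xhat.begin() + hw * (c + (size_t)C * n);
      const double* gp = g.begin() + hw * (c + (size_t)C * n);
      double sg = 0, sgx = 0;
      for (size_t q = 0; q < hw; ++q) { sg += gp[q]; sgx += gp[q] * xp[q]; }
      dbeta[c] += sg; dgamma[c] += sgx;
    }
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = xhat.begin() + hw * (c + (size_t)C * n);
      const double* gp = g.begin() + hw * (c + (size_t)C * n);
      double* dp = dx.begin() + hw * (c + (size_t)C * n);
      double k = gamma[c] * istd[c];
      if (training) {
        double a = dbeta[c] / m, b = dgamma[c] / m;
        for (size_t q = 0; q < hw; ++q)
          dp[q] = k * (gp[q] - a - xp[q] * b);
      } else {
        for (size_t q = 0; q < hw; ++q) dp[q] = k * gp[q];
      }
    }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = ".relu_fw")]]
NumericVector relu_fw(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  return y;
}

// [[Rcpp::export(name = ".relu_bw")]]
NumericVector relu_bw(NumericVector y, NumericVector g) {
  NumericVector dx(y.size());
  dx.attr("dim") = y.attr("dim");
  for (R_xlen_t i = 0; i < y.size(); ++i) dx[i] = y[i] > 0 ? g[i] : 0.0;
  return dx;
}

// x * alpha[c, n] broadcast over pixels
// [[Rcpp::export(name = ".chan_mul")]]
NumericVector chan_mul(NumericVector x, NumericMatrix alpha) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t hw = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + hw * (c + (size_t)C * n);
      double* yp = y.begin() + hw * (c + (size_t)C * n);
      double a = alpha(c, n);
      for (size_t q = 0; q < hw; ++q) yp[q] = xp[q] * a;
    }
  return y;
}

// sum over pixels of a * b per (c, n)
// [[Rcpp::export(name = ".chan_dot")]]
NumericMatrix chan_dot(NumericVector a, NumericVector b) {
  IntegerVector xd = a.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t hw = (size_t)H * W;
  NumericMatrix out(C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* ap = a.begin() + hw * (c + (size_t)C * n);
      const double* bp = b.begin() + hw * (c + (size_t)C * n);
      double s = 0;
      for (size_t q = 0; q < hw; ++q) s += ap[q] * bp[q];
      out(c, n) = s;
    }
  return out;
}
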