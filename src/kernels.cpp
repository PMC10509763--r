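// Low-level numeric kernels: im2col convolutions, 2x2 pooling and transposed
// convolution (the building blocks of the encoder-decoder nets), image
// resampling, connected-component labelling and an exact anisotropic
// Euclidean distance transform. All image arrays are column-major with
// dimensions (H, W, C, N) matching R's array layout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static NumericVector make4(int H, int W, int C, int N) {
  NumericVector v((R_xlen_t)H * W * C * N);
  v.attr("dim") = IntegerVector::create(H, W, C, N);
  return v;
}

// col matrix layout (transposed im2col): col_t is (H*W x C*k*k); column
// r = c*k*k + dj*k + di holds the input shifted by kernel offset (di, dj).
// All writes are contiguous down each column.
static void im2col_t(const double* x, int H, int W, int C, int k, int pad,
                     arma::mat& col) {
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * HW;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        double* dst = col.colptr(c * k * k + dj * k + di);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pad;
          double* d0 = dst + (size_t)j * H;
          if (sj < 0 || sj >= W) {
            std::fill(d0, d0 + H, 0.0);
            continue;
          }
          const double* s0 = x + (size_t)c * HW + (size_t)sj * H;
          const int lo = std::max(0, pad - di);           // rows with si >= 0
          const int hi = std::min(H, H + pad - di);       // rows with si < H
          for (int i = 0; i < lo; ++i) d0[i] = 0.0;
          for (int i = lo; i < hi; ++i) d0[i] = s0[i + di - pad];
          for (int i = hi; i < H; ++i) d0[i] = 0.0;
        }
      }
    }
    (void)xc;
  }
}

static void col2im_t(const arma::mat& col, int H, int W, int C, int k, int pad,
                     double* gx) {
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const double* src = col.colptr(c * k * k + dj * k + di);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          double* d0 = gx + (size_t)c * HW + (size_t)sj * H;
          const double* s0 = src + (size_t)j * H;
          const int lo = std::max(0, pad - di);
          const int hi = std::min(H, H + pad - di);
          for (int i = lo; i < hi; ++i) d0[i + di - pad] += s0[i];
        }
      }
    }
  }
}

// x: (H,W,Cin,N); Wmat: (Cout x Cin*k*k); bias: length Cout. Stride 1,
// pad = (k-1)/2 ("same" output grid).
// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericMatrix Wmat,
                           NumericVector bias, int k) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = Wmat.nrow();
  const int pad = (k - 1) / 2;
  const size_t HW = (size_t)H * W;
  NumericVector out = make4(H, W, Cout, N);
  arma::mat Wm(Wmat.begin(), Cout, Wmat.ncol(), false);
  arma::mat col(HW, (size_t)C * k * k);
  for (int n = 0; n < N; ++n) {
    arma::mat Y(out.begin() + (size_t)n * HW * Cout, HW, Cout, false, true);
    if (k == 1) {
      arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * HW * C, HW, C,
                  false, true);
      Y = X * Wm.t();
    } else {
      im2col_t(x.begin() + (size_t)n * HW * C, H, W, C, k, pad, col);
      Y = col * Wm.t();
    }
    for (int co = 0; co < Cout; ++co) Y.col(co) += bias[co];
  }
  return out;
}

// returns list(gx, gW, gb)
// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericMatrix Wmat, NumericVector gy,
                  int k) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = Wmat.nrow();
  const int pad = (k - 1) / 2;
  const size_t HW = (size_t)H * W;
  NumericVector gx = make4(H, W, C, N);
  NumericMatrix gW(Cout, Wmat.ncol());
  NumericVector gb(Cout);
  arma::mat Wm(Wmat.begin(), Cout, Wmat.ncol(), false);
  arma::mat gWm(gW.begin(), Cout, gW.ncol(), false);
  arma::mat col(HW, (size_t)C * k * k);
  for (int n = 0; n < N; ++n) {
    arma::mat G(const_cast<double*>(gy.begin()) + (size_t)n * HW * Cout, HW,
                Cout, false, true);
    if (k == 1) {
      arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * HW * C, HW, C,
                  false, true);
      gWm += G.t() * X;
      arma::mat GX(gx.begin() + (size_t)n * HW * C, HW, C, false, true);
      GX += G * Wm;
    } else {
      im2col_t(x.begin() + (size_t)n * HW * C, H, W, C, k, pad, col);
      gWm += G.t() * col;
      arma::mat gcol = G * Wm; // (HW x C*k*k)
      col2im_t(gcol, H, W, C, k, pad, gx.begin() + (size_t)n * HW * C);
    }
    for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(G.col(co));
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Returns list(y, argmax) where argmax holds
// 1-based linear indices into x.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int H2 = H / 2, W2 = W / 2;
  NumericVector y = make4(H2, W2, C, N);
  IntegerVector arg(y.size());
  size_t t = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int j = 0; j < W2; ++j)
        for (int i = 0; i < H2; ++i) {
          size_t best = base + (size_t)(2 * j) * H + 2 * i;
          double bv = x[best];
          const size_t cand[3] = {base + (size_t)(2 * j) * H + 2 * i + 1,
                                  base + (size_t)(2 * j + 1) * H + 2 * i,
                                  base + (size_t)(2 * j + 1) * H + 2 * i + 1};
          for (int u = 0; u < 3; ++u)
            if (x[cand[u]] > bv) { bv = x[cand[u]]; best = cand[u]; }
          y[t] = bv;
          arg[t] = (int)(best + 1);
          ++t;
        }
    }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gy, IntegerVector argmax,
                              IntegerVector xdim) {
  NumericVector gx = make4(xdim[0], xdim[1], xdim[2], xdim[3]);
  for (R_xlen_t t = 0; t < gy.size(); ++t)
    gx[argmax[t] - 1] += gy[t];
  return gx;
}

// Transposed convolution, kernel 2x2, stride 2 (each output pixel receives
// exactly one input contribution). Wt: (4*Cout x Cin), row r = (a + 2*b) + 4*co
// for output offset (a,b) within the 2x2 block.
// [[Rcpp::export]]
NumericVector cpp_tconv_fwd(NumericVector x, NumericMatrix Wt,
                            NumericVector bias) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], Cin = d[2], N = d[3];
  const int Cout = Wt.nrow() / 4;
  const int H2 = H * 2, W2 = W * 2;
  const size_t HW = (size_t)H * W;
  NumericVector y = make4(H2, W2, Cout, N);
  arma::mat Wm(Wt.begin(), Wt.nrow(), Cin, false);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * HW * Cin, HW, Cin,
                false, true);
    arma::mat Yt = X * Wm.t(); // (HW x 4Cout)
    double* yn = y.begin() + (size_t)n * (size_t)H2 * W2 * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double b = bias[co];
      for (int bb = 0; bb < 2; ++bb)
        for (int aa = 0; aa < 2; ++aa) {
          const double* src = Yt.colptr(aa + 2 * bb + 4 * co);
          for (int j = 0; j < W; ++j) {
            double* dst = yn + (size_t)co * H2 * W2 + (size_t)(2 * j + bb) * H2 + aa;
            const double* s0 = src + (size_t)j * H;
            for (int i = 0; i < H; ++i) dst[2 * i] = s0[i] + b;
          }
        }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_tconv_bwd(NumericVector x, NumericMatrix Wt, NumericVector gy) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], Cin = d[2], N = d[3];
  const int Cout = Wt.nrow() / 4;
  const int H2 = H * 2, W2 = W * 2;
  const size_t HW = (size_t)H * W;
  NumericVector gx = make4(H, W, Cin, N);
  NumericMatrix gW(Wt.nrow(), Cin);
  NumericVector gb(Cout);
  arma::mat Wm(Wt.begin(), Wt.nrow(), Cin, false);
  arma::mat gWm(gW.begin(), Wt.nrow(), Cin, false);
  arma::mat G4(HW, Wt.nrow());
  for (int n = 0; n < N; ++n) {
    const double* gyn = gy.begin() + (size_t)n * (size_t)H2 * W2 * Cout;
    for (int co = 0; co < Cout; ++co)
      for (int bb = 0; bb < 2; ++bb)
        for (int aa = 0; aa < 2; ++aa) {
          double* dst = G4.colptr(aa + 2 * bb + 4 * co);
          for (int j = 0; j < W; ++j) {
            const double* src = gyn + (size_t)co * H2 * W2 + (size_t)(2 * j + bb) * H2 + aa;
            double* d0 = dst + (size_t)j * H;
            for (int i = 0; i < H; ++i) d0[i] = src[2 * i];
          }
        }
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * HW * Cin, HW, Cin,
                false, true);
    gWm += G4.t() * X;
    arma::mat GX(gx.begin() + (size_t)n * HW * Cin, HW, Cin, false, true);
    GX = G4 * Wm;
    for (int co = 0; co < Cout; ++co)
      for (int r = 4 * co; r < 4 * co + 4; ++r)
        gb[co] += arma::accu(G4.col(r));
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// Bilinear resampling of a single-channel image, half-pixel-center
// convention (identity when sizes are unchanged).
// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(NumericMatrix x, int h2, int w2) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix y(h2, w2);
  const double sr = (double)H / h2, sc = (double)W / w2;
  for (int j = 0; j < w2; ++j) {
    double fc = (j + 0.5) * sc - 0.5;
    if (fc < 0) fc = 0;
    if (fc > W - 1) fc = W - 1;
    const int c0 = (int)fc, c1 = c0 < W - 1 ? c0 + 1 : c0;
    const double wc = fc - c0;
    for (int i = 0; i < h2; ++i) {
      double fr = (i + 0.5) * sr - 0.5;
      if (fr < 0) fr = 0;
      if (fr > H - 1) fr = H - 1;
      const int r0 = (int)fr, r1 = r0 < H - 1 ? r0 + 1 : r0;
      const double wr = fr - r0;
      y(i, j) = (1 - wr) * ((1 - wc) * x(r0, c0) + wc * x(r0, c1)) +
                wr * ((1 - wc) * x(r1, c0) + wc * x(r1, c1));
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericMatrix cpp_resize_nearest(NumericMatrix x, int h2, int w2) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix y(h2, w2);
  const double sr = (double)H / h2, sc = (double)W / w2;
  for (int j = 0; j < w2; ++j) {
    int c = (int)((j + 0.5) * sc);
    if (c > W - 1) c = W - 1;
    for (int i = 0; i < h2; ++i) {
      int r = (int)((i + 0.5) * sr);
      if (r > H - 1) r = H - 1;
      y(i, j) = x(r, c);
    }
  }
  return y;
}

// Connected components of a binary matrix (nonzero = foreground).
// Labels are assigned in column-major discovery order starting at 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  const int d8i[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int d8j[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nd = connectivity == 8 ? 8 : 4;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + H * j);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % H, pj = p / H;
        for (int u = 0; u < nd; ++u) {
          const int qi = pi + d8i[u], qj = pj + d8j[u];
          if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
          if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + H * qj);
          }
        }
      }
    }
  return lab;
}

// Large finite stand-in for "no source in this scan line": keeps the
// parabola intersections finite. Far above any attainable squared mm
// distance, far below sqrt(DBL_MAX).
static const double DT_INF = 1e15;

static void dt1d(const double* f, int n, double w, double* d,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -1e300;
  z[1] = 1e300;
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      const int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (k > 0 && s <= z[k]) { --k; } else break;
    }
    if (s <= z[k]) { v[k] = q; z[k + 1] = 1e300; }
    else { ++k; v[k] = q; z[k] = s; z[k + 1] = 1e300; }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = (double)(q - v[k]) * w;
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every pixel to the nearest
// foreground pixel of `mask`, with per-axis pixel sizes dy (rows) and dx
// (columns). Felzenszwalb-Huttenlocher two-pass algorithm; exact.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(IntegerMatrix mask, double dy, double dx) {
  const int H = mask.nrow(), W = mask.ncol();
  NumericMatrix D(H, W);
  const int m = std::max(H, W);
  std::vector<double> f(m), d(m), z(m + 1);
  std::vector<int> v(m);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) f[i] = mask(i, j) != 0 ? 0.0 : DT_INF;
    dt1d(f.data(), H, dy, d.data(), v, z);
    for (int i = 0; i < H; ++i) D(i, j) = d[i];
  }
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) f[j] = D(i, j);
    dt1d(f.data(), W, dx, d.data(), v, z);
    for (int j = 0; j < W; ++j) D(i, j) = d[j];
  }
  return D;
}

// Channel-wise batch normalization on (H,W,C,N) arrays, avoiding array
// permutations. Train mode: batch statistics (biased variance) plus
// updated running stats; eval mode: the supplied running stats.
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector run_mean, NumericVector run_var,
                bool train, double momentum, double eps) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t HW = (size_t)H * W;
  NumericVector y = make4(H, W, C, N);
  NumericVector mu(C), inv_std(C), new_rm(clone(run_mean)), new_rv(clone(run_var));
  const double M = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    double m_c, v_c;
    if (train) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + ((size_t)n * C + c) * HW;
        for (size_t q = 0; q < HW; ++q) { s += xc[q]; s2 += xc[q] * xc[q]; }
      }
      m_c = s / M;
      v_c = s2 / M - m_c * m_c;
      if (v_c < 0) v_c = 0;
      new_rm[c] = (1 - momentum) * new_rm[c] + momentum * m_c;
      new_rv[c] = (1 - momentum) * new_rv[c] + momentum * v_c;
    } else {
      m_c = run_mean[c];
      v_c = run_var[c];
    }
    const double is = 1.0 / std::sqrt(v_c + eps);
    mu[c] = m_c;
    inv_std[c] = is;
    const double g = gamma[c] * is, b = beta[c] - gamma[c] * is * m_c;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)n * C + c) * HW;
      double* yc = y.begin() + ((size_t)n * C + c) * HW;
      for (size_t q = 0; q < HW; ++q) yc[q] = g * xc[q] + b;
    }
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["inv_std"] = inv_std,
                      _["run_mean"] = new_rm, _["run_var"] = new_rv);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector gy, NumericVector gamma,
                NumericVector mu, NumericVector inv_std, bool train) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t HW = (size_t)H * W;
  NumericVector gx = make4(H, W, C, N);
  NumericVector ggamma(C), gbeta(C);
  const double M = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    const double is = inv_std[c], m_c = mu[c];
    double t1 = 0, t2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)n * C + c) * HW;
      const double* gc = gy.begin() + ((size_t)n * C + c) * HW;
      for (size_t q = 0; q < HW; ++q) {
        const double xh = (xc[q] - m_c) * is;
        t1 += gc[q];
        t2 += gc[q] * xh;
      }
    }
    gbeta[c] = t1;
    ggamma[c] = t2;
    const double g = gamma[c];
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)n * C + c) * HW;
      const double* gc = gy.begin() + ((size_t)n * C + c) * HW;
      double* oc = gx.begin() + ((size_t)n * C + c) * HW;
      if (train) {
        for (size_t q = 0; q < HW; ++q) {
          const double xh = (xc[q] - m_c) * is;
          oc[q] = g * is * (gc[q] - t1 / M - xh * t2 / M);
        }
      } else {
        for (size_t q = 0; q < HW; ++q) oc[q] = g * is * gc[q];
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}
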