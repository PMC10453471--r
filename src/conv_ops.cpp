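// Convolution primitives with explicit forward and backward passes.
//
// Tensor layout (matches the R side):
//   2D feature maps: array dim (H, W, C)        -> arma::cube (rows, cols, slices)
//   3D feature maps: array dim (D, H, W, C)     -> flat vector with dim attribute
//
// Dense conv weights are stored as a (kh*kw*cin) x cout matrix whose row index
// runs ki (fastest), kj, ci — the same order the im2col buffer is filled in.
// Depthwise weights are (kh*kw) x C. All convolutions use symmetric zero
// padding of floor(effective_kernel / 2), so stride-1 output extents equal the
// input and stride-2 extents are ceil(n / 2) for odd effective kernels.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_extent(int n, int k_eff, int stride, int pad) {
  return (n + 2 * pad - k_eff) / stride + 1;
}

// Fill one block of the im2col buffer: output columns [c0, c1).
static void im2col_block(const arma::cube& x, arma::mat& col,
                         int kh, int kw, int stride, int dil, int pad,
                         int Hout, int c0, int c1) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  for (int n = c0; n < c1; ++n) {
    const int ho = n % Hout, wo = n / Hout;
    const int hbase = ho * stride - pad, wbase = wo * stride - pad;
    double* dst = col.colptr(n - c0);
    int r = 0;
    for (int ci = 0; ci < C; ++ci) {
      const arma::mat& xc = x.slice(ci);
      for (int kj = 0; kj < kw; ++kj) {
        const int wi = wbase + kj * dil;
        const bool wok = wi >= 0 && wi < W;
        for (int ki = 0; ki < kh; ++ki, ++r) {
          const int hi = hbase + ki * dil;
          dst[r] = (wok && hi >= 0 && hi < H) ? xc(hi, wi) : 0.0;
        }
      }
    }
  }
}

static void col2im_block(arma::cube& dx, const arma::mat& dcol,
                         int kh, int kw, int stride, int dil, int pad,
                         int Hout, int c0, int c1) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  for (int n = c0; n < c1; ++n) {
    const int ho = n % Hout, wo = n / Hout;
    const int hbase = ho * stride - pad, wbase = wo * stride - pad;
    const double* src = dcol.colptr(n - c0);
    int r = 0;
    for (int ci = 0; ci < C; ++ci) {
      arma::mat& xc = dx.slice(ci);
      for (int kj = 0; kj < kw; ++kj) {
        const int wi = wbase + kj * dil;
        const bool wok = wi >= 0 && wi < W;
        for (int ki = 0; ki < kh; ++ki, ++r) {
          const int hi = hbase + ki * dil;
          if (wok && hi >= 0 && hi < H) xc(hi, wi) += src[r];
        }
      }
    }
  }
}

static const int COL_BLOCK = 16384;  // bounds im2col memory at ~K*16384 doubles

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b, int kh, int kw,
                          int stride, int dil) {
  const int keffh = (kh - 1) * dil + 1, keffw = (kw - 1) * dil + 1;
  const int pad = keffh / 2;  // square kernels in practice
  const int Hout = out_extent(x.n_rows, keffh, stride, pad);
  const int Wout = out_extent(x.n_cols, keffw, stride, pad);
  const int K = kh * kw * x.n_slices, N = Hout * Wout, Cout = w.n_cols;
  arma::cube y(Hout, Wout, Cout);
  arma::mat col(K, std::min(N, COL_BLOCK));
  for (int c0 = 0; c0 < N; c0 += COL_BLOCK) {
    const int c1 = std::min(N, c0 + COL_BLOCK);
    if (c1 - c0 != (int)col.n_cols) col.set_size(K, c1 - c0);
    im2col_block(x, col, kh, kw, stride, dil, pad, Hout, c0, c1);
    arma::mat yb = w.t() * col;            // Cout x block
    yb.each_col() += b;
    for (int co = 0; co < Cout; ++co) {
      double* ys = y.slice(co).memptr();
      for (int n = c0; n < c1; ++n) ys[n] = yb(co, n - c0);
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& w,
                    const arma::cube& dy, int kh, int kw,
                    int stride, int dil) {
  const int keffh = (kh - 1) * dil + 1, keffw = (kw - 1) * dil + 1;
  const int pad = keffh / 2;
  const int Hout = dy.n_rows, Wout = dy.n_cols, Cout = dy.n_slices;
  const int K = kh * kw * x.n_slices, N = Hout * Wout;
  arma::cube dx(x.n_rows, x.n_cols, x.n_slices, arma::fill::zeros);
  arma::mat dw(K, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat col(K, std::min(N, COL_BLOCK));
  for (int c0 = 0; c0 < N; c0 += COL_BLOCK) {
    const int c1 = std::min(N, c0 + COL_BLOCK);
    if (c1 - c0 != (int)col.n_cols) col.set_size(K, c1 - c0);
    im2col_block(x, col, kh, kw, stride, dil, pad, Hout, c0, c1);
    arma::mat dyb(Cout, c1 - c0);
    for (int co = 0; co < Cout; ++co) {
      const double* ys = dy.slice(co).memptr();
      for (int n = c0; n < c1; ++n) dyb(co, n - c0) = ys[n];
    }
    dw += col * dyb.t();
    db += arma::sum(dyb, 1);
    arma::mat dcol = w * dyb;              // K x block
    col2im_block(dx, dcol, kh, kw, stride, dil, pad, Hout, c0, c1);
  }
  (void)keffw;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Depthwise 2D convolution: one k x k filter per channel.
// [[Rcpp::export]]
arma::cube cpp_dwconv2d_fwd(const arma::cube& x, const arma::mat& w,
                            const arma::vec& b, int k, int stride, int dil) {
  const int keff = (k - 1) * dil + 1, pad = keff / 2;
  const int Hout = out_extent(x.n_rows, keff, stride, pad);
  const int Wout = out_extent(x.n_cols, keff, stride, pad);
  const int C = x.n_slices, H = x.n_rows, W = x.n_cols;
  arma::cube y(Hout, Wout, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    arma::mat& yc = y.slice(c);
    const double bc = b(c);
    for (int wo = 0; wo < Wout; ++wo) {
      const int wbase = wo * stride - pad;
      for (int ho = 0; ho < Hout; ++ho) {
        const int hbase = ho * stride - pad;
        double acc = bc;
        int r = 0;
        for (int kj = 0; kj < k; ++kj) {
          const int wi = wbase + kj * dil;
          if (wi < 0 || wi >= W) { r += k; continue; }
          for (int ki = 0; ki < k; ++ki, ++r) {
            const int hi = hbase + ki * dil;
            if (hi >= 0 && hi < H) acc += w(r, c) * xc(hi, wi);
          }
        }
        yc(ho, wo) = acc;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv2d_bwd(const arma::cube& x, const arma::mat& w,
                      const arma::cube& dy, int k, int stride, int dil) {
  const int keff = (k - 1) * dil + 1, pad = keff / 2;
  const int Hout = dy.n_rows, Wout = dy.n_cols;
  const int C = x.n_slices, H = x.n_rows, W = x.n_cols;
  arma::cube dx(H, W, C, arma::fill::zeros);
  arma::mat dw(k * k, C, arma::fill::zeros);
  arma::vec db(C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    arma::mat& dxc = dx.slice(c);
    const arma::mat& dyc = dy.slice(c);
    for (int wo = 0; wo < Wout; ++wo) {
      const int wbase = wo * stride - pad;
      for (int ho = 0; ho < Hout; ++ho) {
        const int hbase = ho * stride - pad;
        const double g = dyc(ho, wo);
        db(c) += g;
        int r = 0;
        for (int kj = 0; kj < k; ++kj) {
          const int wi = wbase + kj * dil;
          if (wi < 0 || wi >= W) { r += k; continue; }
          for (int ki = 0; ki < k; ++ki, ++r) {
            const int hi = hbase + ki * dil;
            if (hi >= 0 && hi < H) {
              dw(r, c) += g * xc(hi, wi);
              dxc(hi, wi) += g * w(r, c);
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---- 3D convolution (stride 1, cubic kernel, same padding) ----
// x: flat vector with dims (D, H, W, C); w: (k^3 * cin) x cout.

static void im2col3d_block(const double* x, arma::mat& col,
                           int D, int H, int W, int C, int k, int pad,
                           int c0, int c1) {
  const long DH = (long)D * H, DHW = DH * W;
  for (int n = c0; n < c1; ++n) {
    int rem = n;
    const int dn = rem % D; rem /= D;
    const int ho = rem % H; rem /= H;
    const int wo = rem;
    double* dst = col.colptr(n - c0);
    int r = 0;
    for (int ci = 0; ci < C; ++ci) {
      const double* xc = x + (long)ci * DHW;
      for (int kw_ = 0; kw_ < k; ++kw_) {
        const int wi = wo - pad + kw_;
        const bool wok = wi >= 0 && wi < W;
        for (int kh_ = 0; kh_ < k; ++kh_) {
          const int hi = ho - pad + kh_;
          const bool hok = hi >= 0 && hi < H;
          for (int kd = 0; kd < k; ++kd, ++r) {
            const int di = dn + kd - pad;
            dst[r] = (wok && hok && di >= 0 && di < D)
              ? xc[di + (long)hi * D + (long)wi * DH] : 0.0;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(const NumericVector& x, const arma::mat& w,
                             const arma::vec& b, int k) {
  IntegerVector dm = x.attr("dim");
  const int D = dm[0], H = dm[1], W = dm[2], C = dm[3];
  const int pad = k / 2, Cout = w.n_cols;
  const int N = D * H * W, K = k * k * k * C;
  NumericVector y(N * (long)Cout);
  arma::mat col(K, std::min(N, COL_BLOCK));
  for (int c0 = 0; c0 < N; c0 += COL_BLOCK) {
    const int c1 = std::min(N, c0 + COL_BLOCK);
    if (c1 - c0 != (int)col.n_cols) col.set_size(K, c1 - c0);
    im2col3d_block(x.begin(), col, D, H, W, C, k, pad, c0, c1);
    arma::mat yb = w.t() * col;
    yb.each_col() += b;
    for (int co = 0; co < Cout; ++co) {
      double* ys = y.begin() + (long)co * N;
      for (int n = c0; n < c1; ++n) ys[n] = yb(co, n - c0);
    }
  }
  y.attr("dim") = IntegerVector::create(D, H, W, Cout);
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(const NumericVector& x, const arma::mat& w,
                    const NumericVector& dy, int k) {
  IntegerVector dm = x.attr("dim");
  const int D = dm[0], H = dm[1], W = dm[2], C = dm[3];
  const int pad = k / 2, Cout = w.n_cols;
  const int N = D * H * W, K = k * k * k * C;
  NumericVector dx(x.size());
  arma::mat dw(K, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  const long DH = (long)D * H, DHW = DH * W;
  arma::mat col(K, std::min(N, COL_BLOCK));
  for (int c0 = 0; c0 < N; c0 += COL_BLOCK) {
    const int c1 = std::min(N, c0 + COL_BLOCK);
    if (c1 - c0 != (int)col.n_cols) col.set_size(K, c1 - c0);
    im2col3d_block(x.begin(), col, D, H, W, C, k, pad, c0, c1);
    arma::mat dyb(Cout, c1 - c0);
    for (int co = 0; co < Cout; ++co) {
      const double* ys = dy.begin() + (long)co * N;
      for (int n = c0; n < c1; ++n) dyb(co, n - c0) = ys[n];
    }
    dw += col * dyb.t();
    db += arma::sum(dyb, 1);
    arma::mat dcol = w * dyb;
    // scatter back (col2im, 3D)
    for (int n = c0; n < c1; ++n) {
      int rem = n;
      const int dn = rem % D; rem /= D;
      const int hn = rem % H; rem /= H;
      const int wn = rem;
      const double* src = dcol.colptr(n - c0);
      int r = 0;
      for (int ci = 0; ci < C; ++ci) {
        double* xc = dx.begin() + (long)ci * DHW;
        for (int kw_ = 0; kw_ < k; ++kw_) {
          const int wi = wn - pad + kw_;
          const bool wok = wi >= 0 && wi < W;
          for (int kh_ = 0; kh_ < k; ++kh_) {
            const int hi = hn - pad + kh_;
            const bool hok = hi >= 0 && hi < H;
            for (int kd = 0; kd < k; ++kd, ++r) {
              const int di = dn + kd - pad;
              if (wok && hok && di >= 0 && di < D)
                xc[di + (long)hi * D + (long)wi * DH] += src[r];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = dm;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
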