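#include <Rcpp.h>
using namespace Rcpp;

// Dense 2-D cross-correlation ("convolution" in the CNN sense) on arrays in
// (H, W, C, N) layout with kernels in (K, K, C, D) layout. Plain loops are
// fast enough at the feature-map sizes this package trains on and keep the
// arithmetic bit-reproducible across platforms.

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// im2col / col2im: convolution is lowered to one BLAS matrix product in R.
// Rows of the patch matrix are indexed by (io, jo, n) with io fastest; its
// columns by (ki, kj, c), matching the (K, K, C, D) kernel layout, so
//   y = patches %*% matrix(w, K*K*C, D).
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int K1, int K2, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = out_size(H, K1, stride, pad), Wo = out_size(W, K2, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");
  const R_xlen_t nrow = static_cast<R_xlen_t>(Ho) * Wo * N;
  NumericMatrix col(nrow, K1 * K2 * C);
  const double *px = x.begin();
  double *pc = col.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < K2; ++kj) {
      for (int ki = 0; ki < K1; ++ki) {
        double *dst = pc + (static_cast<R_xlen_t>(c) * K1 * K2 + kj * K1 + ki) * nrow;
        for (int n = 0; n < N; ++n) {
          const double *xc = px + (static_cast<R_xlen_t>(n) * C + c) * H * W;
          double *drow = dst + static_cast<R_xlen_t>(n) * Ho * Wo;
          for (int jo = 0; jo < Wo; ++jo) {
            const int j = jo * stride - pad + kj;
            double *dcol = drow + static_cast<R_xlen_t>(jo) * Ho;
            if (j < 0 || j >= W) {
              for (int io = 0; io < Ho; ++io) dcol[io] = 0.0;
              continue;
            }
            const double *xcol = xc + static_cast<R_xlen_t>(j) * H;
            for (int io = 0; io < Ho; ++io) {
              const int i = io * stride - pad + ki;
              dcol[io] = (i >= 0 && i < H) ? xcol[i] : 0.0;
            }
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix gcol, int K1, int K2, int stride,
                         int pad, int H, int W, int C, int N) {
  const int Ho = out_size(H, K1, stride, pad), Wo = out_size(W, K2, stride, pad);
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const R_xlen_t nrow = static_cast<R_xlen_t>(Ho) * Wo * N;
  const double *pc = gcol.begin();
  double *px = gx.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < K2; ++kj) {
      for (int ki = 0; ki < K1; ++ki) {
        const double *src = pc + (static_cast<R_xlen_t>(c) * K1 * K2 + kj * K1 + ki) * nrow;
        for (int n = 0; n < N; ++n) {
          double *xc = px + (static_cast<R_xlen_t>(n) * C + c) * H * W;
          const double *srow = src + static_cast<R_xlen_t>(n) * Ho * Wo;
          for (int jo = 0; jo < Wo; ++jo) {
            const int j = jo * stride - pad + kj;
            if (j < 0 || j >= W) continue;
            const double *scol = srow + static_cast<R_xlen_t>(jo) * Ho;
            double *xcol = xc + static_cast<R_xlen_t>(j) * H;
            for (int io = 0; io < Ho; ++io) {
              const int i = io * stride - pad + ki;
              if (i >= 0 && i < H) xcol[i] += scol[io];
            }
          }
        }
      }
    }
  }
  return gx;
}

// Bilinear resize with half-pixel centre alignment and edge clamping,
// applied per channel and batch item on (H, W, C, N) arrays.
// [[Rcpp::export]]
NumericVector cpp_bilinear_resize(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double sh = static_cast<double>(H) / Ho, sw = static_cast<double>(W) / Wo;
  std::vector<int> i0v(Ho), i1v(Ho), j0v(Wo), j1v(Wo);
  std::vector<double> tiv(Ho), tjv(Wo);
  for (int io = 0; io < Ho; ++io) {
    double src = (io + 0.5) * sh - 0.5;
    if (src < 0) src = 0;
    if (src > H - 1) src = H - 1;
    i0v[io] = static_cast<int>(std::floor(src));
    i1v[io] = std::min(i0v[io] + 1, H - 1);
    tiv[io] = src - i0v[io];
  }
  for (int jo = 0; jo < Wo; ++jo) {
    double src = (jo + 0.5) * sw - 0.5;
    if (src < 0) src = 0;
    if (src > W - 1) src = W - 1;
    j0v[jo] = static_cast<int>(std::floor(src));
    j1v[jo] = std::min(j0v[jo] + 1, W - 1);
    tjv[jo] = src - j0v[jo];
  }
  const double *px = x.begin();
  double *py = y.begin();
  for (R_xlen_t cn = 0; cn < static_cast<R_xlen_t>(C) * N; ++cn) {
    const double *xc = px + cn * H * W;
    double *yc = py + cn * Ho * Wo;
    for (int jo = 0; jo < Wo; ++jo) {
      const int j0 = j0v[jo], j1 = j1v[jo];
      const double tj = tjv[jo];
      for (int io = 0; io < Ho; ++io) {
        const int i0 = i0v[io], i1 = i1v[io];
        const double ti = tiv[io];
        const double v00 = xc[i0 + static_cast<R_xlen_t>(j0) * H];
        const double v10 = xc[i1 + static_cast<R_xlen_t>(j0) * H];
        const double v01 = xc[i0 + static_cast<R_xlen_t>(j1) * H];
        const double v11 = xc[i1 + static_cast<R_xlen_t>(j1) * H];
        yc[io + static_cast<R_xlen_t>(jo) * Ho] =
          (1 - ti) * (1 - tj) * v00 + ti * (1 - tj) * v10 +
          (1 - ti) * tj * v01 + ti * tj * v11;
      }
    }
  }
  return y;
}

// Average pooling with zero padding counted in the divisor (so it is exactly
// the convolution with a diagonal 1/K^2 kernel, as used by the collapse of
// the pooling branch into a single kernel).
// [[Rcpp::export]]
NumericVector cpp_avgpool_fwd(NumericVector x, int K, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = out_size(H, K, stride, pad), Wo = out_size(W, K, stride, pad);
  if (Ho < 1 || Wo < 1) stop("avgpool: output size would be empty");
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double inv = 1.0 / (K * K);
  const double *px = x.begin();
  double *py = y.begin();
  for (R_xlen_t cn = 0; cn < static_cast<R_xlen_t>(C) * N; ++cn) {
    const double *xc = px + cn * H * W;
    double *yc = py + cn * Ho * Wo;
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        double acc = 0.0;
        const int i0 = io * stride - pad, j0 = jo * stride - pad;
        for (int kj = 0; kj < K; ++kj) {
          const int j = j0 + kj;
          if (j < 0 || j >= W) continue;
          for (int ki = 0; ki < K; ++ki) {
            const int i = i0 + ki;
            if (i < 0 || i >= H) continue;
            acc += xc[i + static_cast<R_xlen_t>(j) * H];
          }
        }
        yc[io + static_cast<R_xlen_t>(jo) * Ho] = acc * inv;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_bwd(NumericVector gy, int K, int stride, int pad,
                              int H, int W) {
  IntegerVector gd = gy.attr("dim");
  const int Ho = gd[0], Wo = gd[1], C = gd[2], N = gd[3];
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double inv = 1.0 / (K * K);
  const double *pg = gy.begin();
  double *px = gx.begin();
  for (R_xlen_t cn = 0; cn < static_cast<R_xlen_t>(C) * N; ++cn) {
    const double *gc = pg + cn * Ho * Wo;
    double *xc = px + cn * H * W;
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        const double g = gc[io + static_cast<R_xlen_t>(jo) * Ho] * inv;
        if (g == 0.0) continue;
        const int i0 = io * stride - pad, j0 = jo * stride - pad;
        for (int kj = 0; kj < K; ++kj) {
          const int j = j0 + kj;
          if (j < 0 || j >= W) continue;
          for (int ki = 0; ki < K; ++ki) {
            const int i = i0 + ki;
            if (i < 0 || i >= H) continue;
            xc[i + static_cast<R_xlen_t>(j) * H] += g;
          }
        }
      }
    }
  }
  return gx;
}

// Max pooling, forward only (used by the resnet18-style stem, which this
// package builds for architecture inspection and inference, not training).
// [[Rcpp::export]]
NumericVector cpp_maxpool_fwd(NumericVector x, int K, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = out_size(H, K, stride, pad), Wo = out_size(W, K, stride, pad);
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *px = x.begin();
  double *py = y.begin();
  for (R_xlen_t cn = 0; cn < static_cast<R_xlen_t>(C) * N; ++cn) {
    const double *xc = px + cn * H * W;
    double *yc = py + cn * Ho * Wo;
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        double best = R_NegInf;
        const int i0 = io * stride - pad, j0 = jo * stride - pad;
        for (int kj = 0; kj < K; ++kj) {
          const int j = j0 + kj;
          if (j < 0 || j >= W) continue;
          for (int ki = 0; ki < K; ++ki) {
            const int i = i0 + ki;
            if (i < 0 || i >= H) continue;
            const double v = xc[i + static_cast<R_xlen_t>(j) * H];
            if (v > best) best = v;
          }
        }
        yc[io + static_cast<R_xlen_t>(jo) * Ho] = best;
      }
    }
  }
  return y;
}
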