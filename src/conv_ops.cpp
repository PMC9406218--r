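// Grouped 2-D convolution kernels (im2col + GEMM) and connected-component
// labelling. Tensor layout throughout: column-major R arrays of dimension
// (H, W, C, N), so each channel plane is a contiguous H*W block.
// Weight layout: (k, k, Cin/groups, Cout); column-major, so the weights for
// one group's output channels form a contiguous (k*k*Cg) x (Co/groups) block.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill the im2col matrix (HoWo x k*k*Cg) for image n, group g.
static void im2col_fill(const double* x, arma::mat& col,
                        int H, int W, int C, int n, int g, int Cg,
                        int k, int stride, int pad, int Ho, int Wo) {
  for (int ci = 0; ci < Cg; ++ci) {
    const int c = g * Cg + ci;
    const double* xp = x + (static_cast<size_t>(n) * C + c) *
                           static_cast<size_t>(H) * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * (kw + k * ci);
        double* cp = col.colptr(r);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho) cp[ho + Ho * wo] = 0.0;
            continue;
          }
          const double* xcol = xp + static_cast<size_t>(H) * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + kh;
            cp[ho + Ho * wo] = (hi >= 0 && hi < H) ? xcol[hi] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add the columns matrix back onto the input gradient (col2im).
static void col2im_add(double* gx, const arma::mat& col,
                       int H, int W, int C, int n, int g, int Cg,
                       int k, int stride, int pad, int Ho, int Wo) {
  for (int ci = 0; ci < Cg; ++ci) {
    const int c = g * Cg + ci;
    double* xp = gx + (static_cast<size_t>(n) * C + c) *
                      static_cast<size_t>(H) * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * (kw + k * ci);
        const double* cp = col.colptr(r);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xp + static_cast<size_t>(H) * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + kh;
            if (hi >= 0 && hi < H) xcol[hi] += cp[ho + Ho * wo];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw_cpp(NumericVector x, NumericVector w,
                            int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cg = wd[2], Co = wd[3];
  if (wd[1] != k) stop("non-square kernel");
  if (C != Cg * groups || Co % groups != 0)
    stop("channel/group mismatch in conv2d");
  const int Ho = conv_out_dim(H, k, stride, pad);
  const int Wo = conv_out_dim(W, k, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv output would be empty");
  const int Cog = Co / groups;

  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);

  arma::mat col(static_cast<size_t>(Ho) * Wo, static_cast<size_t>(k) * k * Cg);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col_fill(x.begin(), col, H, W, C, n, g, Cg, k, stride, pad, Ho, Wo);
      const arma::mat Wg(const_cast<double*>(w.begin()) +
                           static_cast<size_t>(k) * k * Cg * (g * Cog),
                         static_cast<size_t>(k) * k * Cg, Cog, false, true);
      arma::mat Y = col * Wg;  // (HoWo x Cog), channel planes contiguous
      std::copy(Y.begin(), Y.end(),
                y.begin() + (static_cast<size_t>(n) * Co + g * Cog) *
                            static_cast<size_t>(Ho) * Wo);
    }
  }
  return y;
}

// Gradient w.r.t. the input: gy (Ho,Wo,Co,N) -> gx (H,W,C,N).
// [[Rcpp::export]]
NumericVector conv2d_bwin_cpp(NumericVector gy, NumericVector w,
                              int H, int W, int stride, int pad, int groups) {
  IntegerVector gd = gy.attr("dim"), wd = w.attr("dim");
  const int Ho = gd[0], Wo = gd[1], Co = gd[2], N = gd[3];
  const int k = wd[0], Cg = wd[2];
  const int C = Cg * groups, Cog = Co / groups;
  if (Ho != conv_out_dim(H, k, stride, pad) ||
      Wo != conv_out_dim(W, k, stride, pad))
    stop("gradient spatial dims inconsistent with H/W");

  NumericVector gx(static_cast<R_xlen_t>(H) * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);

  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      const arma::mat GY(const_cast<double*>(gy.begin()) +
                           (static_cast<size_t>(n) * Co + g * Cog) *
                           static_cast<size_t>(Ho) * Wo,
                         static_cast<size_t>(Ho) * Wo, Cog, false, true);
      const arma::mat Wg(const_cast<double*>(w.begin()) +
                           static_cast<size_t>(k) * k * Cg * (g * Cog),
                         static_cast<size_t>(k) * k * Cg, Cog, false, true);
      arma::mat GCol = GY * Wg.t();
      col2im_add(gx.begin(), GCol, H, W, C, n, g, Cg, k, stride, pad, Ho, Wo);
    }
  }
  return gx;
}

// Gradient w.r.t. the weights, accumulated over the batch.
// [[Rcpp::export]]
NumericVector conv2d_bww_cpp(NumericVector x, NumericVector gy,
                             int k, int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim"), gd = gy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = gd[0], Wo = gd[1], Co = gd[2];
  const int Cg = C / groups, Cog = Co / groups;

  NumericVector gw(static_cast<R_xlen_t>(k) * k * Cg * Co);
  gw.attr("dim") = IntegerVector::create(k, k, Cg, Co);

  arma::mat col(static_cast<size_t>(Ho) * Wo, static_cast<size_t>(k) * k * Cg);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col_fill(x.begin(), col, H, W, C, n, g, Cg, k, stride, pad, Ho, Wo);
      const arma::mat GY(const_cast<double*>(gy.begin()) +
                           (static_cast<size_t>(n) * Co + g * Cog) *
                           static_cast<size_t>(Ho) * Wo,
                         static_cast<size_t>(Ho) * Wo, Cog, false, true);
      arma::mat GWg(gw.begin() + static_cast<size_t>(k) * k * Cg * (g * Cog),
                    static_cast<size_t>(k) * k * Cg, Cog, false, true);
      GWg += col.t() * GY;
    }
  }
  return gw;
}

// Connected-component labelling of a binary mask. Components are labelled
// 1..M in raster order (row by row, left to right) of their first pixel.
// connectivity: 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(IntegerMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dh4[] = {-1, 1, 0, 0}, dw4[] = {0, 0, -1, 1};
  const int dh8[] = {-1, -1, -1, 0, 0, 1, 1, 1},
            dw8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int nd = (connectivity == 4) ? 4 : 8;
  const int* dh = (connectivity == 4) ? dh4 : dh8;
  const int* dw = (connectivity == 4) ? dw4 : dw8;
  int next = 0;
  std::vector<int> stack;
  for (int h = 0; h < H; ++h) {
    for (int w = 0; w < W; ++w) {
      if (mask(h, w) == 0 || lab(h, w) != 0) continue;
      ++next;
      lab(h, w) = next;
      stack.clear();
      stack.push_back(h + H * w);
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int ch = idx % H, cw = idx / H;
        for (int d = 0; d < nd; ++d) {
          const int nh = ch + dh[d], nw = cw + dw[d];
          if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
          if (mask(nh, nw) != 0 && lab(nh, nw) == 0) {
            lab(nh, nw) = next;
            stack.push_back(nh + H * nw);
          }
        }
      }
    }
  }
  return lab;
}
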