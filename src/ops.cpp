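#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Layout convention: feature batches are numeric arrays dim (H, W, C, N),
// column-major as R stores them. "Same" padding for odd k is (k-1)/2 zeros.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int k) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int pad = (k - 1) / 2;
  const R_xlen_t rows = (R_xlen_t)H * W * N;
  NumericMatrix out(rows, k * k * C);
  const double* px = x.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int j = kh + k * kw + k * k * c;
        double* col = po + (R_xlen_t)j * rows;
        for (int n = 0; n < N; ++n) {
          const double* xc = px + ((R_xlen_t)n * C + c) * H * W;
          for (int w = 0; w < W; ++w) {
            const int sw = w + kw - pad;
            R_xlen_t r = (R_xlen_t)n * H * W + (R_xlen_t)w * H;
            if (sw < 0 || sw >= W) {
              for (int h = 0; h < H; ++h) col[r + h] = 0.0;
            } else {
              const double* src = xc + (R_xlen_t)sw * H;
              for (int h = 0; h < H; ++h) {
                const int sh = h + kh - pad;
                col[r + h] = (sh < 0 || sh >= H) ? 0.0 : src[sh];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C, int N, int k) {
  const int pad = (k - 1) / 2;
  const R_xlen_t rows = (R_xlen_t)H * W * N;
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  double* pdx = dx.begin();
  const double* pc = cols.begin();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int j = kh + k * kw + k * k * c;
        const double* col = pc + (R_xlen_t)j * rows;
        for (int n = 0; n < N; ++n) {
          double* xc = pdx + ((R_xlen_t)n * C + c) * H * W;
          for (int w = 0; w < W; ++w) {
            const int sw = w + kw - pad;
            if (sw < 0 || sw >= W) continue;
            const R_xlen_t r = (R_xlen_t)n * H * W + (R_xlen_t)w * H;
            double* dst = xc + (R_xlen_t)sw * H;
            for (int h = 0; h < H; ++h) {
              const int sh = h + kh - pad;
              if (sh >= 0 && sh < H) dst[sh] += col[r + h];
            }
          }
        }
      }
    }
  }
  return dx;
}

// 2x2 max pooling, stride 2; also returns 0-based argmax indices into x.
// [[Rcpp::export]]
List cpp_maxpool(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  const double* px = x.begin();
  double* py = y.begin();
  int* pi = idx.begin();
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = ((R_xlen_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          R_xlen_t i00 = base + (R_xlen_t)(2 * w) * H + 2 * h;
          R_xlen_t best = i00;
          double v = px[i00];
          if (px[i00 + 1] > v) { v = px[i00 + 1]; best = i00 + 1; }
          if (px[i00 + H] > v) { v = px[i00 + H]; best = i00 + H; }
          if (px[i00 + H + 1] > v) { v = px[i00 + H + 1]; best = i00 + H + 1; }
          py[o] = v;
          pi[o] = (int)best;
          ++o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  const double* pdy = dy.begin();
  const int* pi = idx.begin();
  double* pdx = dx.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) pdx[pi[i]] += pdy[i];
  return dx;
}

// Median filter over a k x k window (k odd), replicate border.
// [[Rcpp::export]]
NumericMatrix cpp_median_blur(NumericMatrix x, int k) {
  const int H = x.nrow(), W = x.ncol(), r = (k - 1) / 2;
  NumericMatrix out(H, W);
  std::vector<double> win((size_t)k * k);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      size_t m = 0;
      for (int dw = -r; dw <= r; ++dw) {
        int sw = std::min(std::max(w + dw, 0), W - 1);
        for (int dh = -r; dh <= r; ++dh) {
          int sh = std::min(std::max(h + dh, 0), H - 1);
          win[m++] = x(sh, sw);
        }
      }
      std::nth_element(win.begin(), win.begin() + m / 2, win.begin() + m);
      out(h, w) = win[m / 2];
    }
  return out;
}

// 8-connected components of a {0,255} raster; labels 1..n, 0 = background.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix x) {
  const int H = x.nrow(), W = x.ncol();
  IntegerMatrix lab(H, W);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      if (x(h, w) == 0 || lab(h, w) != 0) continue;
      ++next;
      stack.push_back((R_xlen_t)w * H + h);
      lab(h, w) = next;
      while (!stack.empty()) {
        R_xlen_t p = stack.back(); stack.pop_back();
        int ph = (int)(p % H), pw = (int)(p / H);
        for (int dw = -1; dw <= 1; ++dw)
          for (int dh = -1; dh <= 1; ++dh) {
            int nh = ph + dh, nw = pw + dw;
            if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
            if (x(nh, nw) != 0 && lab(nh, nw) == 0) {
              lab(nh, nw) = next;
              stack.push_back((R_xlen_t)nw * H + nh);
            }
          }
      }
    }
  return lab;
}
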