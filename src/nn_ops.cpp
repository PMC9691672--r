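#include <Rcpp.h>
using namespace Rcpp;

// im2col for 3x3 same-padding convolution on an H x W x C array.
// Output is (H*W) x (9*C); column (c-1)*9 + o holds kernel offset o of
// channel c, with o - 1 = (dr + 1) + 3*(dc + 1), dr/dc in {-1,0,1}.
// [[Rcpp::export(name = ".im2col3")]]
NumericMatrix im2col3(NumericVector x, int H, int W, int C) {
  NumericMatrix col(H * W, 9 * C);
  const double *px = x.begin();
  double *pc = col.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = px + (size_t)c * H * W;
    for (int o = 0; o < 9; ++o) {
      int dr = o % 3 - 1, dc = o / 3 - 1;
      double *out = pc + ((size_t)c * 9 + o) * H * W;
      for (int j = 0; j < W; ++j) {
        int sj = j + dc;
        if (sj < 0 || sj >= W) continue;
        const double *src = xc + (size_t)sj * H;
        double *dst = out + (size_t)j * H;
        int i0 = dr < 0 ? 1 : 0;
        int i1 = dr > 0 ? H - 1 : H;
        for (int i = i0; i < i1; ++i) dst[i] = src[i + dr];
      }
    }
  }
  return col;
}

// Scatter-add transpose of im2col3: accumulates a (H*W) x (9*C) gradient
// back into an H x W x C array.
// [[Rcpp::export(name = ".col2im3")]]
NumericVector col2im3(NumericMatrix dcol, int H, int W, int C) {
  NumericVector dx((size_t)H * W * C);
  const double *pc = dcol.begin();
  double *px = dx.begin();
  for (int c = 0; c < C; ++c) {
    double *xc = px + (size_t)c * H * W;
    for (int o = 0; o < 9; ++o) {
      int dr = o % 3 - 1, dc = o / 3 - 1;
      const double *in = pc + ((size_t)c * 9 + o) * H * W;
      for (int j = 0; j < W; ++j) {
        int sj = j + dc;
        if (sj < 0 || sj >= W) continue;
        double *dst = xc + (size_t)sj * H;
        const double *src = in + (size_t)j * H;
        int i0 = dr < 0 ? 1 : 0;
        int i1 = dr > 0 ? H - 1 : H;
        for (int i = i0; i < i1; ++i) dst[i + dr] += src[i];
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}
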