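#include <Rcpp.h>
using namespace Rcpp;

// Fused zero-pad + im2col lowering for a 3x3 same convolution on a
// channel-first (C, H, W, B) feature map. Produces the (9C) x (H*W*B)
// matrix whose row r = (k-1)*C + ci with k enumerating offsets dh fastest,
// matching the weight layout used by the R training code. Doing the pad
// and gather in one pass (instead of allocating a padded copy and
// gathering through a cached index vector) roughly halves the memory
// traffic of a training iteration.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(const NumericVector& x, int C, int H, int W, int B) {
  const int HW = H * W;
  NumericMatrix out(no_init(9 * C, HW * B));
  const double* xp = x.begin();
  double* op = out.begin();
  const int nrow = 9 * C;
  for (int b = 0; b < B; ++b) {
    const double* xb = xp + (R_xlen_t)b * C * HW;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double* col = op + (R_xlen_t)nrow * (b * HW + w * H + h);
        for (int dw = 0; dw < 3; ++dw) {
          const int iw = w + dw - 1;
          for (int dh = 0; dh < 3; ++dh) {
            const int ih = h + dh - 1;
            double* dst = col + (dh + 3 * dw) * C;
            if (ih < 0 || ih >= H || iw < 0 || iw >= W) {
              for (int ci = 0; ci < C; ++ci) dst[ci] = 0.0;
            } else {
              const double* src = xb + (R_xlen_t)C * (ih + iw * H);
              for (int ci = 0; ci < C; ++ci) dst[ci] = src[ci];
            }
          }
        }
      }
    }
  }
  return out;
}
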