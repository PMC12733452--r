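#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Unfold a (H, W, B, C) feature map into the (H*W*B) x (kh*kw*C) patch
// matrix of a same-padding dilated convolution.  Row r corresponds to the
// spatial/batch location (y, x, b) with y fastest; column order is
// (ki, kj, ci) with ki fastest, matching an R-side reshape of a
// (kh, kw, Cin, Cout) kernel into (kh*kw*Cin) x Cout.  Out-of-image taps
// are zero; the matrix is allocated uninitialized and every entry is
// written exactly once.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int B, int C,
                         int kh, int kw, int dil) {
  const R_xlen_t HWB = (R_xlen_t)H * W * B;
  NumericMatrix out = no_init(HWB, (R_xlen_t)kh * kw * C);
  const double* px = x.begin();
  double* po = out.begin();
  const int cy = (kh - 1) / 2, cx = (kw - 1) / 2;
  for (int ci = 0; ci < C; ++ci) {
    for (int kj = 0; kj < kw; ++kj) {
      const int ox = (kj - cx) * dil;
      for (int ki = 0; ki < kh; ++ki) {
        const int oy = (ki - cy) * dil;
        const R_xlen_t col = ki + (R_xlen_t)kh * (kj + (R_xlen_t)kw * ci);
        double* ocol = po + col * HWB;
        int y0 = oy < 0 ? -oy : 0;
        int y1 = oy > 0 ? H - oy : H;
        if (y1 < y0) { y0 = 0; y1 = 0; }
        for (int b = 0; b < B; ++b) {
          for (int xx = 0; xx < W; ++xx) {
            const int sx = xx + ox;
            double* dst = ocol + (R_xlen_t)H * (xx + (R_xlen_t)W * b);
            if (sx < 0 || sx >= W || y1 <= y0) {
              std::memset(dst, 0, sizeof(double) * H);
              continue;
            }
            if (y0 > 0) std::memset(dst, 0, sizeof(double) * y0);
            const double* src = px + (R_xlen_t)(y0 + oy) +
              (R_xlen_t)H * (sx + (R_xlen_t)W * (b + (R_xlen_t)B * ci));
            std::memcpy(dst + y0, src, sizeof(double) * (y1 - y0));
            if (y1 < H) std::memset(dst + y1, 0, sizeof(double) * (H - y1));
          }
        }
      }
    }
  }
  return out;
}
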