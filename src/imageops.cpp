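// Bilinear affine warp on the package's coordinate convention:
// 0-based (row, col), pixel centers at integer coordinates.
// For every output pixel (r, c) the source location is
//   (r_in, c_in) = A %*% c(r, c) + b
// and the output intensity is the bilinear interpolation of the input
// there (0 outside the input grid).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export(name = ".warp_affine_cpp")]]
NumericMatrix warp_affine_cpp(NumericMatrix img, NumericMatrix A,
                              NumericVector b, int out_rows, int out_cols) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(out_rows, out_cols);
  const double a11 = A(0, 0), a12 = A(0, 1), a21 = A(1, 0), a22 = A(1, 1);
  const double b1 = b[0], b2 = b[1];
  for (int c = 0; c < out_cols; ++c) {
    for (int r = 0; r < out_rows; ++r) {
      const double ri = a11 * r + a12 * c + b1;
      const double ci = a21 * r + a22 * c + b2;
      if (ri < 0 || ci < 0 || ri > H - 1 || ci > W - 1) continue;
      int r0 = (int)std::floor(ri), c0 = (int)std::floor(ci);
      if (r0 == H - 1) r0--;
      if (c0 == W - 1) c0--;
      if (r0 < 0) r0 = 0;
      if (c0 < 0) c0 = 0;
      const double fr = ri - r0, fc = ci - c0;
      out(r, c) = (1 - fr) * (1 - fc) * img(r0, c0) +
                  fr * (1 - fc) * img(r0 + 1, c0) +
                  (1 - fr) * fc * img(r0, c0 + 1) +
                  fr * fc * img(r0 + 1, c0 + 1);
    }
  }
  return out;
}
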