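// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Symmetric reflection (edge sample included) of an out-of-range index,
// valid for any padding width: ..., 2, 1, 0 | 0, 1, ..., n-1 | n-1, n-2, ...
static inline arma::uword reflect_index(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return static_cast<arma::uword>(i < n ? i : period - 1 - i);
}

// Extend an image by h pixels on every side using symmetric reflection.
static arma::mat reflect_pad(const arma::mat& x, int h) {
  const int nr = x.n_rows, nc = x.n_cols;
  arma::mat out(nr + 2 * h, nc + 2 * h);
  for (int c = -h; c < nc + h; ++c) {
    const arma::uword cc = reflect_index(c, nc);
    for (int r = -h; r < nr + h; ++r) {
      out(r + h, c + h) = x(reflect_index(r, nr), cc);
    }
  }
  return out;
}

// 2-D cross-correlation (no kernel flip) of a real image with a complex
// kernel, same-size output, borders handled by symmetric reflection.
// kre/kim are the real and imaginary kernel parts on an odd square grid.
// The padded image is materialised once; each output pixel is then a
// plain dot product between the kernel and an aligned image window.
// [[Rcpp::export(name = ".xcorr2_reflect")]]
List xcorr2_reflect(const arma::mat& image, const arma::mat& kre,
                    const arma::mat& kim) {
  const arma::uword ks = kre.n_rows;
  if (kre.n_cols != ks || kim.n_rows != ks || kim.n_cols != ks ||
      ks % 2 == 0) {
    stop("kernel must be square with odd side length");
  }
  const int h = static_cast<int>(ks / 2);
  const arma::uword nr = image.n_rows, nc = image.n_cols;

  const arma::mat padded = reflect_pad(image, h);
  arma::mat out_re(nr, nc), out_im(nr, nc);
  for (arma::uword c = 0; c < nc; ++c) {
    for (arma::uword r = 0; r < nr; ++r) {
      // window rows r..r+ks-1, cols c..c+ks-1 of the padded image is the
      // reflected neighbourhood of (r, c) in the original image
      double acc_re = 0.0, acc_im = 0.0;
      for (arma::uword kc = 0; kc < ks; ++kc) {
        const double* win = padded.colptr(c + kc) + r;
        const double* wre = kre.colptr(kc);
        const double* wim = kim.colptr(kc);
        for (arma::uword kr = 0; kr < ks; ++kr) {
          acc_re += win[kr] * wre[kr];
          acc_im += win[kr] * wim[kr];
        }
      }
      out_re(r, c) = acc_re;
      out_im(r, c) = acc_im;
    }
  }
  return List::create(_["re"] = wrap(out_re), _["im"] = wrap(out_im));
}
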