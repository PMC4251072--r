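// Fused application of the 2D Gabor wavelet filter bank.
// For each scale the per-pixel maximum of the response modulus over all
// orientations is accumulated in one pass, avoiding 90 intermediate
// full-size maps on the R side.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static vec freq_grid(int n) {
  vec k(n);
  int half = n / 2;
  for (int i = 0; i <= half; ++i) k(i) = 2.0 * datum::pi * i / n;
  for (int i = half + 1; i < n; ++i) k(i) = 2.0 * datum::pi * (i - n) / n;
  return k;
}

// F: centred-free forward FFT of the image (ny x nx, unnormalized as from
// stats::fft).  Returns a cube (ny, nx, n_scales): per-scale orientation
// maxima of |CWT|.  The analysing wavelet in the frequency domain is the
// unit-peak Gaussian exp(-0.5 * |A^{-1}(a R_{-theta} k - k0)|^2) with
// A^{-1} = diag(sqrt(eps), 1) (unit-peak = L1 envelope normalization).
// [[Rcpp::export]]
arma::cube gabor_bank_max_cpp(const arma::cx_mat& F,
                              const arma::vec& scales,
                              const arma::vec& angles_deg,
                              double eps, const arma::vec& k0) {
  const int ny = F.n_rows, nx = F.n_cols;
  const vec ky = freq_grid(ny), kx = freq_grid(nx);
  cube out(ny, nx, scales.n_elem, fill::zeros);
  cx_mat G(ny, nx);
  for (uword s = 0; s < scales.n_elem; ++s) {
    const double a = scales(s);
    for (uword t = 0; t < angles_deg.n_elem; ++t) {
      const double th = angles_deg(t) * datum::pi / 180.0;
      const double c = std::cos(th), sn = std::sin(th);
      for (int j = 0; j < nx; ++j) {
        for (int i = 0; i < ny; ++i) {
          const double u1 = a * (c * kx(j) + sn * ky(i)) - k0(0);
          const double u2 = a * (-sn * kx(j) + c * ky(i)) - k0(1);
          const double e = -0.5 * (eps * u1 * u1 + u2 * u2);
          // flush far tails to exact zero: subnormal filter weights make
          // the FFT orders of magnitude slower and contribute nothing
          G(i, j) = (e < -46.0) ? cx_double(0.0, 0.0) : F(i, j) * std::exp(e);
        }
      }
      const mat resp = abs(ifft2(G));
      out.slice(s) = max(out.slice(s), resp);
    }
  }
  return out;
}
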