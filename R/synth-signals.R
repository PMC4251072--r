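#' Fractional Brownian motion series of known fractal dimension
#'
#' Generates an fBm path with Hurst exponent `hurst` by exact circulant
#' embedding (Davies-Harte) of the fractional Gaussian noise covariance,
#' then cumulative summation.  The graph of the path has theoretical
#' fractal dimension `2 - hurst`, which makes it the reference fixture for
#' the Higuchi estimator.
#'
#' @param hurst Hurst exponent, strictly inside (0, 1).
#' @param n series length, at least 64.
#' @param seed integer RNG seed; identical inputs give identical series.
#' @param method `"circulant"` (exact Davies-Harte, default) or
#'   `"cholesky"` (dense factorization, limited to `n <= 2048`).
#' @return Numeric vector of length `n`.
#' @examples
#' x <- gen_fbm_series(0.5, 512, seed = 1)
#' @export
gen_fbm_series <- function(hurst, n, seed, method = c("circulant", "cholesky")) {
  if (!is.numeric(hurst) || length(hurst) != 1 || hurst <= 0 || hurst >= 1)
    stop("`hurst` must lie strictly inside (0, 1)")
  if (n < 64) stop("`n` must be at least 64")
  method <- match.arg(method)
  fgn <- with_seed(seed, {
    if (method == "circulant") fgn_circulant(hurst, n) else fgn_cholesky(hurst, n)
  })
  cumsum(fgn)
}

## autocovariance of unit-variance fractional Gaussian noise at lag k
fgn_acov <- function(k, hurst) {
  h2 <- 2 * hurst
  0.5 * (abs(k + 1)^h2 - 2 * abs(k)^h2 + abs(k - 1)^h2)
}

## Davies-Harte sampling of n fGn increments (exact covariance)
fgn_circulant <- function(hurst, n) {
  g <- n
  cvec <- c(fgn_acov(0:g, hurst), fgn_acov((g - 1):1, hurst))
  m <- 2 * g
  lam <- Re(fft(cvec))
  if (min(lam) < -1e-8 * max(lam)) {
    if (n <= 2048) return(fgn_cholesky(hurst, n))
    stop("circulant embedding not nonnegative definite for these parameters")
  }
  lam[lam < 0] <- 0
  w <- complex(length.out = m)
  w[1] <- rnorm(1)
  w[g + 1] <- rnorm(1)
  ab <- matrix(rnorm(2 * (g - 1)), nrow = 2)
  w[2:g] <- complex(real = ab[1, ], imaginary = ab[2, ]) / sqrt(2)
  w[(g + 2):m] <- Conj(w[g:2])
  x <- Re(fft(sqrt(lam) * w)) / sqrt(m)
  x[seq_len(n)]
}

fgn_cholesky <- function(hurst, n) {
  if (n > 2048) stop("cholesky fGn sampling is limited to n <= 2048")
  sig <- stats::toeplitz(fgn_acov(0:(n - 1), hurst))
  L <- chol(sig)
  as.vector(crossprod(L, rnorm(n)))
}

#' Sierpinski-triangle raster of known box-counting dimension
#'
#' Builds the discrete Sierpinski triangle on a `2^order` square grid
#' (pixel `(i, j)` is foreground iff `bitwAnd(i, j) == 0`).  The set is
#' exactly self-similar with similarity dimension `log(3)/log(2)` and
#' foreground count `3^order`, so box counts are analytic.
#'
#' @param order recursion depth, 1 to 9.
#' @return Integer 0/1 matrix of side `2^order`.
#' @examples
#' sum(gen_sierpinski(3)) == 3^3
#' @export
gen_sierpinski <- function(order) {
  if (order < 1 || order > 9 || order != round(order))
    stop("`order` must be an integer in 1..9")
  m <- 2^order
  idx <- 0:(m - 1)
  out <- outer(idx, idx, function(i, j) as.integer(bitwAnd(i, j) == 0L))
  out
}

#' Random image with power-law radial spectrum
#'
#' Filters white Gaussian noise in the Fourier domain with radial amplitude
#' proportional to `f^(-beta/2)` (DC removed), so the radially averaged
#' log-power spectrum of the result has slope `-beta` against log frequency.
#' Used as the construction oracle for the spectral fractal dimension.
#'
#' @param beta spectral power-law exponent, `>= 0`.
#' @param size image side in pixels, `>= 64` (even).
#' @param seed integer RNG seed.
#' @return Numeric `size x size` matrix (zero mean).
#' @export
gen_power_law_image <- function(beta, size, seed) {
  if (beta < 0) stop("`beta` must be nonnegative")
  if (size < 64) stop("`size` must be at least 64")
  if (size %% 2 != 0) stop("`size` must be even")
  half <- size / 2
  k <- c(0:half, -(half - 1):-1)       # integer wavenumbers, cycles/image
  f <- sqrt(outer(k^2, k^2, "+"))
  amp <- f
  amp[1, 1] <- 1
  amp <- amp^(-beta / 2)
  amp[1, 1] <- 0
  noise <- with_seed(seed, matrix(rnorm(size * size), size, size))
  Re(fft(fft(noise) * amp, inverse = TRUE)) / size^2
}
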