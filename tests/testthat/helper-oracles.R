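# Independent reference implementations used to cross-check the package.
# These are deliberately written as plain, slow transcriptions of the
# defining formulas, sharing no code with the implementations they test.

# Higuchi (1988) curve-length estimator, literal double loop
oracle_higuchi <- function(x, k_max = 8) {
  N <- length(x)
  logL <- numeric(k_max)
  for (k in 1:k_max) {
    Lm <- numeric(k)
    for (m in 1:k) {
      n_m <- floor((N - m) / k)
      total <- 0
      for (i in 1:n_m) {
        total <- total + abs(x[m + i * k] - x[m + (i - 1) * k])
      }
      Lm[m] <- (total * (N - 1) / (n_m * k)) / k
    }
    logL[k] <- log(mean(Lm))
  }
  lx <- log(1:k_max)
  b <- sum((lx - mean(lx)) * logL) / sum((lx - mean(lx))^2)
  -b
}

# Kruskal-Wallis H (tie-corrected) by direct rank arithmetic
oracle_kw_H <- function(groups) {
  pooled <- unlist(groups)
  N <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 0
  for (j in seq_along(groups)) {
    Rj <- sum(r[idx == j])
    H <- H + Rj^2 / sum(idx == j)
  }
  H <- 12 / (N * (N + 1)) * H - 3 * (N + 1)
  tt <- table(pooled)
  H / (1 - sum(tt^3 - tt) / (N^3 - N))
}

# permutation null of H for two small groups (exact enumeration)
oracle_kw_perm_p <- function(a, b) {
  pooled <- c(a, b)
  N <- length(pooled)
  H_obs <- oracle_kw_H(list(a, b))
  combs <- utils::combn(N, length(a))
  Hs <- apply(combs, 2, function(ix)
    oracle_kw_H(list(pooled[ix], pooled[-ix])))
  mean(Hs >= H_obs - 1e-12)
}

# radially averaged Fourier magnitude by direct binning
oracle_radial_magnitude <- function(img) {
  n <- nrow(img)
  mag <- Mod(fft(img - mean(img)))
  half <- n %/% 2
  k <- c(0:half, seq_len(n - half - 1) - (n - half))
  out_f <- integer(0); out_m <- numeric(0)
  f2 <- outer(k^2, k^2, "+")
  for (fr in 1:half) {
    sel <- round(sqrt(f2)) == fr
    out_f <- c(out_f, fr)
    out_m <- c(out_m, mean(mag[sel]))
  }
  data.frame(freq = out_f, magnitude = out_m)
}

# direct spatial-domain Gabor response at selected pixels, with the kernel
# sampled on the periodic torus (matches the FFT implementation's borders)
oracle_gabor_at <- function(img, scale, angle, px, py,
                            elongation = 4, k0 = c(0, 3)) {
  ny <- nrow(img); nx <- ncol(img)
  th <- angle * pi / 180
  xs <- 0:(nx - 1); ys <- 0:(ny - 1)
  vapply(seq_along(px), function(t) {
    dx <- (xs - px[t] + nx / 2) %% nx - nx / 2
    dy <- (ys - py[t] + ny / 2) %% ny - ny / 2
    DX <- matrix(dx, ny, nx, byrow = TRUE)
    DY <- matrix(dy, ny, nx)
    # rotate into the wavelet frame, then dilate
    rx <- (cos(th) * DX + sin(th) * DY) / scale
    ry <- (-sin(th) * DX + cos(th) * DY) / scale
    env <- exp(-0.5 * (rx^2 / elongation + ry^2))
    carrier <- exp(1i * (k0[1] * rx + k0[2] * ry))
    # L1-style normalization: unit-peak frequency response equals
    # envelope mass 1/(2 pi sqrt(eps) scale^2) per unit area
    w <- Conj(carrier) * env / (2 * pi * sqrt(elongation) * scale^2)
    Mod(sum(img * w))
  }, numeric(1))
}

# box counts by explicit per-box scanning (grid anchored at origin)
oracle_box_counts <- function(bin, sides) {
  n <- nrow(bin)
  vapply(sides, function(s) {
    cnt <- 0
    for (bx in seq(1, n, by = s)) {
      for (by in seq(1, n, by = s)) {
        blk <- bin[by:min(by + s - 1, n), bx:min(bx + s - 1, n)]
        if (any(blk > 0)) cnt <- cnt + 1
      }
    }
    cnt
  }, numeric(1))
}
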