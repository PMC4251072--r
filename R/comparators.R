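#' Spectral (Fourier) fractal dimension
#'
#' Radially averages the Fourier magnitude spectrum of a greyscale image
#' and fits an ordinary least-squares line to log magnitude against log
#' radial frequency.  The absolute fitted slope is returned; an optional
#' affine remapping (`offset + scale * |slope|`) is exposed because no
#' canonical slope-to-dimension formula is imposed.
#'
#' @param img square numeric matrix (side `>= 64`) or a
#'   `vessel_posterior`.
#' @param fit_band length-2 frequency band (cycles/image) used in the fit;
#'   default `c(4, 0.45 * size/2)`.
#' @param offset,scale affine remapping of the absolute slope.
#' @return Object of class `sfd`: list with `value`, the raw `slope`, the
#'   fit band, and `diagnostics` (radially averaged magnitudes with fitted
#'   values and residuals).
#' @export
spectral_fd <- function(img, fit_band = NULL, offset = 0, scale = 1) {
  if (inherits(img, "vessel_posterior")) img <- img$pixels
  n <- nrow(img)
  if (n != ncol(img)) stop("`img` must be square")
  if (n < 64) stop("`img` must be at least 64 pixels per side")
  if (sd(img) == 0) stop("constant image has a degenerate spectrum")
  if (is.null(fit_band)) fit_band <- c(4, 0.45 * n / 2)

  mag <- Mod(fft(img - mean(img)))
  half <- floor(n / 2)
  k <- c(0:half, seq_len(n - half - 1) - (n - half))
  f <- sqrt(outer(k^2, k^2, "+"))
  rb <- round(as.vector(f))
  keep <- rb >= 1 & rb <= half
  radial <- vapply(split(as.vector(mag)[keep], rb[keep]), mean, numeric(1))
  freq <- as.numeric(names(radial))

  in_band <- freq >= fit_band[1] & freq <= fit_band[2]
  if (sum(in_band) < 3) stop("fit band contains fewer than 3 frequencies")
  lx <- log(freq[in_band]); ly <- log(radial[in_band])
  slope <- ls_slope(lx, ly)
  fitted <- mean(ly) + slope * (lx - mean(lx))
  structure(list(value = offset + scale * abs(slope), slope = slope,
                 fit_band = fit_band,
                 diagnostics = data.frame(freq = freq, magnitude = radial,
                                          in_band = in_band,
                                          fitted = NA_real_,
                                          residual = NA_real_)),
            class = "sfd") -> out
  out$diagnostics$fitted[in_band] <- fitted
  out$diagnostics$residual[in_band] <- ly - fitted
  out
}

#' @export
print.sfd <- function(x, ...) {
  cat(sprintf("Spectral FD: %.4f (log-magnitude slope %.4f over %.0f-%.1f cycles/image)\n",
              x$value, x$slope, x$fit_band[1], x$fit_band[2]))
  invisible(x)
}

#' Binarize a posterior vessel image for box counting
#'
#' Global Otsu thresholding of the 0-255 vessel-likelihood image, followed
#' by optional morphological skeletonization (Zhang-Suen thinning, on by
#' default) so the box counter sees a one-pixel-wide vascular network.
#'
#' @param img a `vessel_posterior` or numeric matrix.
#' @param method `"otsu"` (default) or `"fixed"` (then give `threshold`).
#' @param threshold fixed threshold on the image's own scale.
#' @param skeletonize logical, default `TRUE`.
#' @return Integer 0/1 matrix.
#' @export
binarize_for_bc <- function(img, method = c("otsu", "fixed"), threshold = NULL,
                            skeletonize = TRUE) {
  method <- match.arg(method)
  if (inherits(img, "vessel_posterior")) img <- img$pixels
  rng <- if (max(img) > 1) 255 else 1
  x <- img / rng
  if (method == "otsu") {
    threshold <- EBImage::otsu(EBImage::Image(x), range = c(0, 1), levels = 256)
  } else {
    if (is.null(threshold)) stop("`threshold` required for method = \"fixed\"")
    threshold <- threshold / rng
  }
  bin <- x > threshold
  if (!any(bin)) stop("binarization produced an empty foreground")
  if (skeletonize) bin <- zhang_suen_thin(bin)
  matrix(as.integer(bin), nrow(img), ncol(img))
}

#' Zhang-Suen morphological thinning
#'
#' Iteratively peels boundary pixels of a binary image until every stroke
#' is one pixel wide, preserving connectivity.
#'
#' @param bin logical or 0/1 matrix.
#' @param max_iter safety cap on thinning passes.
#' @return Logical matrix.
#' @export
zhang_suen_thin <- function(bin, max_iter = 200) {
  zhang_suen_cpp(bin > 0, as.integer(max_iter))
}

#' Box-counting fractal dimension of a binary image
#'
#' Superimposes grids of boxes with side lengths 2, 4, ..., up to a
#' quarter of the image side (powers of two, anchored at the origin),
#' counts the boxes containing at least one foreground pixel, and fits a
#' least-squares line to `log N(s)` against `log(1/s)`.
#'
#' @param bin logical or 0/1 matrix with at least one foreground pixel and
#'   side at least 32 (so the regression has at least 3 points).
#' @return Object of class `bcfd`: list with `value` and `diagnostics`
#'   (box sides and counts).
#' @export
box_counting_fd <- function(bin) {
  if (!any(bin > 0)) stop("need at least one foreground pixel")
  side <- max(nrow(bin), ncol(bin))
  if (min(nrow(bin), ncol(bin)) < 32) stop("image side must be at least 32")
  ## pad to a power-of-two square, grid anchored at the origin
  m <- 2^ceiling(log2(side))
  B <- matrix(FALSE, m, m)
  B[seq_len(nrow(bin)), seq_len(ncol(bin))] <- bin > 0
  sides <- 2^seq_len(floor(log2(side / 4)))
  counts <- integer(length(sides))
  M <- B
  for (i in seq_along(sides)) {
    half <- dim(M)[1] / 2
    odd <- seq_len(half) * 2 - 1
    M <- M[odd, , drop = FALSE] | M[odd + 1, , drop = FALSE]
    M <- M[, odd, drop = FALSE] | M[, odd + 1, drop = FALSE]
    counts[i] <- sum(M)
  }
  if (sum(bin > 0) == 1)
    warning("single foreground pixel: box-counting FD is 0")
  fd <- ls_slope(log(1 / sides), log(counts))
  structure(list(value = fd,
                 diagnostics = data.frame(box_side = sides, n_boxes = counts)),
            class = "bcfd")
}

#' @export
print.bcfd <- function(x, ...) {
  cat(sprintf("Box-counting FD: %.4f (box sides %s)\n", x$value,
              paste(x$diagnostics$box_side, collapse = ", ")))
  invisible(x)
}
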