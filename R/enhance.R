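#' Parameters of the Gabor wavelet filter bank
#'
#' The bank is a directional matched filter for vessels: an oriented,
#' elongated complex wavelet evaluated at several dilations, with the
#' per-pixel maximum taken over orientations.  Defaults follow the
#' standard retinal-enhancement setting: scales 4-8, 18 orientations
#' (10 degree steps from 0 to 170), elongation 4 and wave vector (0, 3).
#'
#' @param scales numeric vector of positive wavelet dilations.
#' @param n_orientations number of equally spaced orientations over
#'   `[0, 180)` degrees.
#' @param elongation envelope anisotropy `epsilon >= 1` (the envelope is
#'   stretched by `sqrt(elongation)` along the vessel direction).
#' @param k0 length-2 wave vector of the complex carrier, radians/pixel at
#'   scale 1.
#' @param include_intensity_feature if `TRUE` (default) the inverted-green
#'   intensity itself is appended to the wavelet features before the
#'   mixture model.
#' @return Object of class `gabor_bank_params`.
#' @export
gabor_bank_params <- function(scales = 4:8, n_orientations = 18,
                              elongation = 4, k0 = c(0, 3),
                              include_intensity_feature = TRUE) {
  if (any(scales <= 0)) stop("`scales` must be positive")
  if (n_orientations < 1) stop("`n_orientations` must be at least 1")
  if (elongation < 1) stop("`elongation` must be >= 1")
  if (length(k0) != 2) stop("`k0` must have length 2")
  structure(list(scales = as.numeric(scales),
                 n_orientations = as.integer(n_orientations),
                 elongation = as.numeric(elongation), k0 = as.numeric(k0),
                 include_intensity_feature = isTRUE(include_intensity_feature)),
            class = "gabor_bank_params")
}

#' Orientations of a bank (degrees)
#' @param params a [gabor_bank_params()] object.
#' @return Numeric vector of orientations in `[0, 180)`.
#' @export
bank_orientations <- function(params) {
  step <- 180 / params$n_orientations
  seq(0, 180 - step, by = step)
}

#' Single Gabor wavelet response
#'
#' Modulus of the continuous wavelet transform of the image at one scale
#' and orientation.  The analysing wavelet is
#' `psi(x) = exp(i k0 . x) exp(-|A x|^2 / 2)` with
#' `A = diag(elongation^(-1/2), 1)`; at orientation `angle` (degrees from
#' the x-axis) it responds maximally to line-like structure oriented along
#' `angle`.  Computed by frequency-domain multiplication (periodic
#' borders); the frequency response is normalized to unit peak, which
#' fixes the L1 norm of the spatial envelope across scales.
#'
#' @param img numeric matrix (finite values).
#' @param scale positive dilation.
#' @param angle orientation in degrees, `[0, 180)`.
#' @param elongation,k0 wavelet shape, see [gabor_bank_params()].
#' @return Non-negative numeric matrix, same shape as `img`.
#' @export
gabor_response <- function(img, scale, angle, elongation = 4, k0 = c(0, 3)) {
  if (!all(is.finite(img))) stop("`img` contains non-finite pixels")
  if (scale <= 0) stop("`scale` must be positive")
  ny <- nrow(img); nx <- ncol(img)
  kx <- freq_grid_r(nx); ky <- freq_grid_r(ny)
  th <- angle * pi / 180
  KX <- matrix(kx, ny, nx, byrow = TRUE)
  KY <- matrix(ky, ny, nx)
  u1 <- scale * (cos(th) * KX + sin(th) * KY) - k0[1]
  u2 <- scale * (-sin(th) * KX + cos(th) * KY) - k0[2]
  e <- -0.5 * (elongation * u1^2 + u2^2)
  psihat <- exp(e)
  psihat[e < -46] <- 0  # flush far tails (subnormals cripple the FFT)
  Mod(fft(fft(img) * psihat, inverse = TRUE)) / (ny * nx)
}

## angular frequencies (rad/pixel) in FFT order
freq_grid_r <- function(n) {
  half <- floor(n / 2)
  2 * pi * c(0:half, seq_len(n - half - 1) - (n - half)) / n
}

#' Per-scale orientation-maximum feature maps
#'
#' Applies the full filter bank and keeps, for each scale, the pixelwise
#' maximum response modulus over all orientations; optionally appends the
#' input intensity as an extra feature.
#'
#' @param img numeric matrix (e.g. the inverted-green working image).
#' @param params a [gabor_bank_params()] object.
#' @return Named list of feature matrices (`scale_4`, ..., and `intensity`
#'   when enabled).
#' @export
max_orientation_features <- function(img, params = gabor_bank_params()) {
  stopifnot(inherits(params, "gabor_bank_params"))
  if (!all(is.finite(img))) stop("`img` contains non-finite pixels")
  F <- fft(img)
  ## arma's ifft2 is normalized, so slices match gabor_response directly
  cube <- gabor_bank_max_cpp(F, params$scales, bank_orientations(params),
                             params$elongation, params$k0)
  feats <- lapply(seq_along(params$scales), function(s) cube[, , s])
  names(feats) <- paste0("scale_", params$scales)
  if (params$include_intensity_feature) feats$intensity <- img
  feats
}

#' Z-score normalization of feature maps
#'
#' Each feature is independently shifted and scaled to zero mean and unit
#' variance over all pixels, making wavelet responses at different scales
#' and the raw intensity commensurate before the mixture model.
#' Zero-variance features are dropped with a warning.
#'
#' @param features named list of numeric matrices of equal shape.
#' @return Named list of normalized matrices.
#' @export
normalize_features <- function(features) {
  if (length(features) < 1) stop("need at least one feature map")
  keep <- vapply(features, function(f) sd(f) > 0, logical(1))
  if (!all(keep))
    warning("dropping zero-variance feature(s): ",
            paste(names(features)[!keep], collapse = ", "))
  features <- features[keep]
  if (length(features) == 0) stop("all features are constant")
  lapply(features, function(f) (f - mean(f)) / sd(f))
}

#' Posterior vessel-likelihood image
#'
#' Fits an unsupervised two-component Gaussian mixture (full covariances,
#' EM with k-means initialization on a random pixel subsample, then
#' evaluated on every pixel) to the normalized per-pixel feature vectors.
#' The component with the higher mean along the largest-scale wavelet
#' feature is taken as the vessel class, and its posterior probability is
#' mapped to the integer range 0-255.
#'
#' @param features named list of normalized feature matrices (see
#'   [normalize_features()]).
#' @param od an [od_annotation()] carried through to the result.
#' @param seed seed for the subsample and k-means initialization.
#' @param n_fit number of pixels in the fitting subsample.
#' @param itmax,tol EM iteration cap and relative loglik tolerance.
#' @return Object of class `vessel_posterior`: list with `pixels` (integer
#'   matrix in 0-255), `od`, and `fit` (mixture parameters or the fallback
#'   marker).
#' @export
posterior_image <- function(features, od, seed = 1, n_fit = 2000,
                            itmax = 100, tol = 1e-6) {
  dims <- dim(features[[1]])
  X <- vapply(features, as.vector, numeric(prod(dims)))
  npix <- nrow(X)
  ## reference feature: largest-scale wavelet response (first scale_*
  ## features are in ascending scale order), else the last feature
  sc <- grep("^scale_", colnames(X))
  ref <- if (length(sc)) max(sc) else ncol(X)

  fit <- tryCatch(
    with_seed(seed, {
      sub <- X[sample.int(npix, min(n_fit, npix)), , drop = FALSE]
      km <- kmeans(sub, centers = 2, nstart = 5)
      z0 <- mclust::unmap(km$cluster)
      ctl <- mclust::emControl(itmax = itmax, tol = tol)
      d <- ncol(X)
      if (d == 1) {
        ms <- mclust::mstepV(data = sub, z = z0)
        em <- mclust::emV(data = sub, parameters = ms$parameters, control = ctl)
      } else {
        ms <- mclust::mstepVVV(data = sub, z = z0)
        em <- mclust::emVVV(data = sub, parameters = ms$parameters, control = ctl)
      }
      par <- em$parameters
      if (is.null(par) || any(!is.finite(par$pro)) || min(par$pro) < 1e-6)
        stop("degenerate mixture fit")
      ## canonical form: mean (d x G), sigma (d x d x G)
      mu <- matrix(par$mean, d, 2)
      sigma <- if (d == 1)
        array(rep_len(par$variance$sigmasq, 2), c(1, 1, 2))
      else par$variance$sigma
      list(pro = par$pro, mean = mu, sigma = sigma)
    }),
    error = function(e) NULL)

  if (is.null(fit)) {
    warning("Gaussian mixture fit degenerate; falling back to percentile stretch")
    p <- (rank(X[, ref], ties.method = "average") - 1) / (npix - 1)
    pixels <- matrix(as.integer(round(255 * p)), dims[1], dims[2])
    return(structure(list(pixels = pixels, od = od, fit = "percentile_stretch"),
                     class = "vessel_posterior"))
  }

  vessel <- which.max(fit$mean[ref, ])
  lp <- vapply(1:2, function(g) {
    mvn_logdensity(X, fit$mean[, g], fit$sigma[, , g, drop = FALSE][, , 1]) +
      log(fit$pro[g])
  }, numeric(npix))
  m <- pmax(lp[, 1], lp[, 2])
  p <- exp(lp[, vessel] - m) / (exp(lp[, 1] - m) + exp(lp[, 2] - m))
  pixels <- matrix(as.integer(round(255 * p)), dims[1], dims[2])
  structure(list(pixels = pixels, od = od, fit = fit),
            class = "vessel_posterior")
}

## multivariate normal log-density, rows of X
mvn_logdensity <- function(X, mu, sigma) {
  d <- length(mu)
  L <- chol(sigma)
  z <- forwardsolve(t(L), t(X) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(L))) - 0.5 * d * log(2 * pi)
}

#' @export
print.vessel_posterior <- function(x, ...) {
  cat(sprintf("Posterior vessel image %dx%d px (0-255); D_OD = %.2f px\n",
              nrow(x$pixels), ncol(x$pixels), x$od$d_od))
  invisible(x)
}

#' Enhance the vessels of a working image
#'
#' Full enhancement chain: Gabor filter bank, per-feature z-normalization,
#' and the two-class Gaussian-mixture posterior.
#'
#' @param wi a `working_image` (see [preprocess_fundus()]).
#' @param params a [gabor_bank_params()] object.
#' @param seed seed for the mixture fit.
#' @param n_fit fitting-subsample size, see [posterior_image()].
#' @return A `vessel_posterior`.
#' @export
enhance_vessels <- function(wi, params = gabor_bank_params(), seed = 1,
                            n_fit = 2000) {
  stopifnot(inherits(wi, "working_image"))
  feats <- max_orientation_features(wi$pixels, params)
  feats <- normalize_features(feats)
  posterior_image(feats, wi$od, seed = seed, n_fit = n_fit)
}
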