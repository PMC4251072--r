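#' Inverted green channel of a colour fundus image
#'
#' The green channel carries the best vessel-to-background contrast in
#' fundus photography; inverting it makes vessels bright.  Inputs on the
#' `[0, 1]` scale (as returned by `png::readPNG`) are first rescaled to
#' `[0, max_value]`.
#'
#' @param rgb 3-channel array `(rows, cols, 3)`.
#' @param max_value intensity ceiling of the image, default 255 (8-bit).
#' @return Numeric matrix `max_value - green`.
#' @export
extract_inverted_green <- function(rgb, max_value = 255) {
  d <- dim(rgb)
  if (length(d) != 3 || d[3] < 3)
    stop("`rgb` must be a 3-channel (rows, cols, 3) array")
  g <- rgb[, , 2]
  if (max(rgb) <= 1) g <- g * max_value
  max_value - g
}

#' Crop the optic-disc-centred region of interest
#'
#' Cuts a square window of side `roi_factor * d_od` centred on the
#' annotated disc centre, covering the circle of `roi_factor` optic-disc
#' diameters the analysis uses, and re-expresses the annotation in crop
#' coordinates (centre at the crop midpoint).
#'
#' @param img greyscale matrix.
#' @param od an [od_annotation()] in `img` coordinates.
#' @param roi_factor window side in optic-disc diameters, default 4.
#' @param pad `"none"` (default; error if the window leaves the frame) or
#'   `"reflect"` (mirror padding).
#' @return List with `image` (cropped matrix) and `od` (shifted annotation).
#' @export
crop_roi <- function(img, od, roi_factor = 4, pad = c("none", "reflect")) {
  pad <- match.arg(pad)
  stopifnot(inherits(od, "od_annotation"))
  side <- round(roi_factor * od$d_od)
  x0 <- round(od$cx - (side - 1) / 2)
  y0 <- round(od$cy - (side - 1) / 2)
  ny <- nrow(img); nx <- ncol(img)
  if (x0 < 0 || y0 < 0 || x0 + side > nx || y0 + side > ny) {
    if (pad == "none")
      stop("ROI window exceeds the frame (optic disc too close to the border); ",
           "use pad = \"reflect\" to allow mirror padding")
    ix <- reflect_index(x0 + 0:(side - 1), nx)
    iy <- reflect_index(y0 + 0:(side - 1), ny)
    out <- img[iy + 1, ix + 1]
  } else {
    out <- img[y0 + 1:side, x0 + 1:side]
  }
  list(image = out, od = od_annotation(od$cx - x0, od$cy - y0, od$d_od))
}

## mirror 0-based indices into [0, n-1]
reflect_index <- function(i, n) {
  per <- 2 * n
  i <- ((i %% per) + per) %% per
  ifelse(i >= n, per - 1 - i, i)
}

#' Area-average downsampling of a square image
#'
#' Resamples to `target_side` pixels per side by exact area averaging
#' (each output pixel is the mean of the input area it covers, with
#' fractional edge weights), which preserves constants exactly and
#' anti-aliases thin vessels.  The annotation is rescaled to the new
#' coordinates under the pixel-centre convention.
#'
#' @param img square greyscale matrix.
#' @param od an [od_annotation()] in `img` coordinates.
#' @param target_side output side in pixels, default 400.
#' @return A `working_image`: list with `pixels`, `od` and `provenance`.
#' @export
downsample <- function(img, od, target_side = 400) {
  ny <- nrow(img); nx <- ncol(img)
  if (ny != nx) stop("`img` must be square")
  if (nx < target_side) stop("input must be at least `target_side` per side")
  if (nx == target_side) {
    out <- img
  } else {
    W <- area_weights(nx, target_side)
    out <- W %*% img %*% t(W)
  }
  sc <- target_side / nx
  od2 <- od_annotation((od$cx + 0.5) * sc - 0.5, (od$cy + 0.5) * sc - 0.5,
                       od$d_od * sc)
  working_image(out, od2, provenance = "downsample")
}

## target x source row matrix of exact area-average weights (rows sum to 1)
area_weights <- function(n_in, n_out) {
  f <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (j in seq_len(n_out)) {
    a <- (j - 1) * f; b <- j * f
    lo <- max(floor(a), 0); hi <- min(ceiling(b) - 1, n_in - 1)
    for (i in lo:hi) {
      W[j, i + 1] <- (min(b, i + 1) - max(a, i)) / f
    }
  }
  W
}

#' Working image container
#'
#' A square greyscale image (higher values = more vessel-like) together
#' with its optic-disc annotation and an ordered record of the processing
#' steps applied.
#'
#' @param pixels numeric matrix.
#' @param od an [od_annotation()].
#' @param provenance character vector of step names.
#' @return Object of class `working_image`.
#' @export
working_image <- function(pixels, od, provenance = character()) {
  if (nrow(pixels) != ncol(pixels)) stop("working image must be square")
  if (od$cx + 2 * od$d_od > ncol(pixels) - 0.5 + 1e-9 ||
      od$cx - 2 * od$d_od < -0.5 - 1e-9 ||
      od$cy + 2 * od$d_od > nrow(pixels) - 0.5 + 1e-9 ||
      od$cy - 2 * od$d_od < -0.5 - 1e-9)
    stop("the 4 x D_OD region of interest does not fit inside the frame")
  structure(list(pixels = pixels, od = od, provenance = provenance),
            class = "working_image")
}

#' @export
print.working_image <- function(x, ...) {
  cat(sprintf("Working image %dx%d px; D_OD = %.2f px; steps: %s\n",
              nrow(x$pixels), ncol(x$pixels), x$od$d_od,
              paste(x$provenance, collapse = " -> ")))
  invisible(x)
}

#' Full preprocessing chain for one fundus image
#'
#' Applies inverted-green extraction (for 3-channel input; greyscale input
#' is treated as an already-extracted green channel and inverted), the
#' 4 x D_OD region-of-interest crop, and area-average downsampling.
#'
#' @param img RGB array or greyscale matrix, values in `[0, 1]` or
#'   `[0, 255]`.
#' @param od an [od_annotation()] in input coordinates.
#' @param roi_factor crop side in optic-disc diameters.
#' @param target_side output resolution, default 400.
#' @param pad border policy passed to [crop_roi()].
#' @return A `working_image` with vessels bright, pixel scale 0-255.
#' @export
preprocess_fundus <- function(img, od, roi_factor = 4, target_side = 400,
                              pad = "none") {
  if (length(dim(img)) == 3) {
    g <- extract_inverted_green(img)
    steps <- "inverted_green"
  } else {
    g <- if (max(img) <= 1) 255 - img * 255 else 255 - img
    steps <- "invert_grey"
  }
  cr <- crop_roi(g, od, roi_factor = roi_factor, pad = pad)
  wi <- downsample(cr$image, cr$od, target_side = target_side)
  wi$provenance <- c(steps, "crop_roi", "downsample")
  wi
}
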