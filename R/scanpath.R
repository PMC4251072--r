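#' Concentric zone specification
#'
#' Zones are annuli measured in optic-disc diameters outward from the disc
#' margin: A = (0, 0.5], B = (0.5, 1.0], C = (1.0, 1.5] (half-open, closed
#' on the right).  The outer edge of C, 1.5 D_OD from the margin, equals
#' radius 2 D_OD from the disc centre, matching the 4 D_OD region of
#' interest.
#'
#' @param bounds numeric vector of zone boundaries in D_OD units from the
#'   margin, default `c(0, 0.5, 1, 1.5)`.
#' @param labels zone labels, one fewer than `bounds`.
#' @return Object of class `zone_spec` (a data frame with columns `zone`,
#'   `lo`, `hi`).
#' @export
zone_spec <- function(bounds = c(0, 0.5, 1, 1.5), labels = c("A", "B", "C")) {
  if (length(labels) != length(bounds) - 1) stop("need one label per interval")
  if (any(diff(bounds) <= 0)) stop("zone boundaries must be strictly increasing")
  structure(data.frame(zone = labels, lo = bounds[-length(bounds)],
                       hi = bounds[-1], stringsAsFactors = FALSE),
            class = c("zone_spec", "data.frame"))
}

#' Radii of the circular scanning paths
#'
#' Integer-pixel radii from one pixel outside the optic-disc boundary to
#' the outermost circle of diameter 4 D_OD: `r = R_OD + 1, ..., 2 * d_od`,
#' with `R_OD = d_od / 2` rounded up to an integer.
#'
#' @param od an [od_annotation()].
#' @param frame_side optional square frame side; if given, the outermost
#'   circle is checked to fit (within the half-pixel border).
#' @return Increasing integer vector of radii in pixels.
#' @export
circle_radii <- function(od, frame_side = NULL) {
  stopifnot(inherits(od, "od_annotation"))
  r0 <- ceiling(od$d_od / 2)
  outer_r <- floor(2 * od$d_od + 1e-9)
  if (!is.null(frame_side)) {
    lim <- min(od$cx, od$cy, frame_side - 1 - od$cx, frame_side - 1 - od$cy) + 0.5
    if (outer_r > lim + 1e-9)
      stop("outermost scanning circle (radius ", outer_r, ") exceeds the frame")
  }
  seq.int(r0 + 1, outer_r)
}

#' Zone label of a scanning circle
#'
#' Classifies a radius by its offset from the optic-disc margin,
#' `(radius - d_od/2) / d_od`, against the half-open zone intervals
#' (closed on the right).
#'
#' @param radius circle radius in pixels (vectorized).
#' @param od an [od_annotation()].
#' @param zones a [zone_spec()].
#' @return Character vector of zone labels.
#' @export
assign_zone <- function(radius, od, zones = zone_spec()) {
  offset <- (radius - od$d_od / 2) / od$d_od
  bad <- offset <= zones$lo[1] + 1e-9 | offset > zones$hi[nrow(zones)] + 1e-9
  if (any(bad))
    stop("radius outside the scanning band (margin offset must lie in (",
         zones$lo[1], ", ", zones$hi[nrow(zones)], "] D_OD)")
  idx <- findInterval(offset - 1e-9, zones$lo)
  zones$zone[idx]
}

#' Sample one circular intensity profile
#'
#' Reads `N ~ 2 * pi * radius` samples at equal angular steps (about one
#' pixel of arc length; `N` is rounded to a multiple of four so that
#' quarter-turn image rotations map the sample grid onto itself exactly)
#' along the circle of the given radius around the optic-disc centre,
#' counter-clockwise from angle 0 (positive x-axis), using clamped
#' bilinear interpolation.
#'
#' @param img numeric matrix or a `vessel_posterior`.
#' @param od an [od_annotation()] (ignored when `img` is a
#'   `vessel_posterior`).
#' @param radius circle radius, pixels.
#' @param zones a [zone_spec()] used to label the profile.
#' @return Object of class `circle_profile`: list with `radius`, `zone`
#'   and `samples`.
#' @export
sample_circle <- function(img, od = NULL, radius, zones = zone_spec()) {
  if (inherits(img, "vessel_posterior")) {
    od <- img$od
    img <- img$pixels
  }
  stopifnot(inherits(od, "od_annotation"))
  lim <- min(od$cx, od$cy, ncol(img) - 1 - od$cx, nrow(img) - 1 - od$cy) + 0.5
  if (radius > lim + 1e-9)
    stop("circle of radius ", radius, " exits the image frame")
  n <- max(16L, 4L * round(pi * radius / 2))
  theta <- 2 * pi * (seq_len(n) - 1) / n
  x <- od$cx + radius * cos(theta)
  y <- od$cy + radius * sin(theta)
  structure(list(radius = radius,
                 zone = assign_zone(radius, od, zones),
                 samples = bilinear_sample(img, x, y)),
            class = "circle_profile")
}

#' Scan all concentric circles of an image
#'
#' Builds the full set of zone-labelled circular profiles for the radii
#' given by [circle_radii()].  The zones partition the circle set.
#'
#' @param img a `vessel_posterior`, `working_image`, or numeric matrix
#'   (then `od` is required).
#' @param od an [od_annotation()] for matrix input.
#' @param zones a [zone_spec()].
#' @return Object of class `circle_scan`: list with `profiles` (list of
#'   `circle_profile`), `od` and `zones`.
#' @export
scan_all <- function(img, od = NULL, zones = zone_spec()) {
  if (inherits(img, "vessel_posterior")) { od <- img$od; img <- img$pixels }
  else if (inherits(img, "working_image")) { od <- img$od; img <- img$pixels }
  stopifnot(inherits(od, "od_annotation"))
  radii <- circle_radii(od, frame_side = nrow(img))
  profiles <- lapply(radii, function(r) sample_circle(img, od, r, zones))
  structure(list(profiles = profiles, od = od, zones = zones),
            class = "circle_scan")
}

#' @export
print.circle_scan <- function(x, ...) {
  zl <- vapply(x$profiles, `[[`, character(1), "zone")
  cat(sprintf("Circular scan: %d circles (%s)\n", length(x$profiles),
              paste(sprintf("%s: %d", names(table(zl)), table(zl)),
                    collapse = ", ")))
  invisible(x)
}

#' Export a circular scan as a long-format data frame
#'
#' One row per sample: `radius, zone, sample_index, value` — the CSV
#' layout used for profile inspection.
#'
#' @param x a `circle_scan`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return A data frame.
#' @export
as.data.frame.circle_scan <- function(x, row.names = NULL, optional = FALSE, ...) {
  do.call(rbind, lapply(x$profiles, function(p)
    data.frame(radius = p$radius, zone = p$zone,
               sample_index = seq_along(p$samples), value = p$samples)))
}
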