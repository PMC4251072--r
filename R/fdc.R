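#' Zone-specific circular fractal dimension (FDC)
#'
#' The package's central estimator.  The image is scanned along concentric
#' circles around the optic disc, Higuchi's fractal dimension is computed
#' for each circular intensity profile, and the per-circle values are
#' averaged within the concentric zones A, B and C and all their
#' combinations (AB, AC, BC, ABC).  A combination's value is the mean over
#' *all* circles in its constituent zones, so with equal circle counts
#' `FDC_AB = (FDC_A + FDC_B) / 2` exactly.
#'
#' @param x a `vessel_posterior` (recommended input: the enhanced
#'   vessel-likelihood image), a `working_image`, a `circle_scan`, or a
#'   numeric matrix (then `od` is required).
#' @param ... passed on between methods.
#' @return Object of class `fdc`: list with `per_circle` (data frame of
#'   radius, zone, sample count and FD per circle), `zone_means` (named
#'   vector over A, B, C, AB, AC, BC, ABC), `k_max`, `n_skipped`
#'   (constant-profile circles excluded) and `od`.
#' @seealso [higuchi_fd()], [scan_all()], [spectral_fd()],
#'   [box_counting_fd()]
#' @examples
#' p <- fundus_synth_params(image_size = 200, od_diameter = 50, seed = 7)
#' synth <- gen_synthetic_fundus(p)
#' ## FD of the raw (inverted) synthetic image, skipping enhancement:
#' wi <- preprocess_fundus(synth$image, synth$od, target_side = 200)
#' fit <- fdc(wi)
#' coef(fit)
#' @export
fdc <- function(x, ...) UseMethod("fdc")

#' @rdname fdc
#' @param od an [od_annotation()] (matrix method only).
#' @param zones a [zone_spec()].
#' @param k_max,fit_range Higuchi settings, see [higuchi_fd()].
#' @export
fdc.matrix <- function(x, od, zones = zone_spec(), k_max = 8,
                       fit_range = seq_len(k_max), ...) {
  fdc(scan_all(x, od, zones), k_max = k_max, fit_range = fit_range)
}

#' @rdname fdc
#' @export
fdc.vessel_posterior <- function(x, zones = zone_spec(), k_max = 8,
                                 fit_range = seq_len(k_max), ...) {
  fdc(scan_all(x, zones = zones), k_max = k_max, fit_range = fit_range)
}

#' @rdname fdc
#' @export
fdc.working_image <- function(x, zones = zone_spec(), k_max = 8,
                              fit_range = seq_len(k_max), ...) {
  fdc(scan_all(x, zones = zones), k_max = k_max, fit_range = fit_range)
}

#' @rdname fdc
#' @export
fdc.circle_scan <- function(x, k_max = 8, fit_range = seq_len(k_max), ...) {
  per <- lapply(x$profiles, function(p) {
    fd <- tryCatch(
      suppressWarnings(as.numeric(higuchi_fd(p$samples, k_max, fit_range))),
      error = function(e) NA_real_)
    data.frame(radius = p$radius, zone = p$zone,
               n_samples = length(p$samples), fd = fd)
  })
  per <- do.call(rbind, per)
  n_skipped <- sum(is.na(per$fd))
  if (n_skipped > 0)
    warning(n_skipped, " constant-profile circle(s) skipped")

  singles <- x$zones$zone
  combos <- c(as.list(singles), utils::combn(singles, 2, simplify = FALSE),
              list(singles))
  names(combos) <- vapply(combos, paste0, character(1), collapse = "")
  zone_means <- vapply(combos, function(zs) {
    v <- per$fd[per$zone %in% zs]
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))

  structure(list(per_circle = per, zone_means = zone_means, k_max = k_max,
                 n_skipped = n_skipped, od = x$od, zones = x$zones),
            class = "fdc")
}

#' @export
print.fdc <- function(x, digits = 4, ...) {
  cat("Zone-specific circular fractal dimension (Higuchi, k_max =",
      x$k_max, ")\n")
  print(round(x$zone_means, digits))
  if (x$n_skipped > 0)
    cat("(", x$n_skipped, "constant-profile circles skipped )\n")
  invisible(x)
}

#' @export
summary.fdc <- function(object, ...) {
  per <- object$per_circle
  zs <- split(per$fd, per$zone)
  cat("Zone-specific circular FD over", nrow(per), "circles",
      sprintf("(D_OD = %.1f px, radii %d..%d)\n", object$od$d_od,
              min(per$radius), max(per$radius)))
  for (z in names(zs)) {
    v <- zs[[z]][!is.na(zs[[z]])]
    cat(sprintf("  zone %s: %3d circles, FD mean %.4f (sd %.4f, range %.4f-%.4f)\n",
                z, length(v), mean(v), sd(v), min(v), max(v)))
  }
  cat("Zone-combination means:\n")
  print(round(object$zone_means, 4))
  invisible(object)
}

#' @export
coef.fdc <- function(object, ...) object$zone_means

#' Plot per-circle Higuchi FD against radius
#'
#' @param x an `fdc` object.
#' @param ... passed to [plot()].
#' @export
plot.fdc <- function(x, ...) {
  per <- x$per_circle
  cols <- c(A = "#D55E00", B = "#009E73", C = "#0072B2")
  plot(per$radius, per$fd, col = cols[per$zone], pch = 16, cex = 0.6,
       xlab = "circle radius (px)", ylab = "Higuchi FD",
       main = "Circular FD profile", ...)
  bounds <- x$od$d_od / 2 + x$zones$hi * x$od$d_od
  abline(v = bounds[-length(bounds)], lty = 3, col = "grey50")
  legend("bottomright", legend = names(cols), col = cols, pch = 16, bty = "n")
  invisible(x)
}
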