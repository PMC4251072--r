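#' Parameters of the synthetic fundus-image generator
#'
#' Bundles and validates the knobs of [gen_synthetic_fundus()].  The
#' geometry follows the optic-disc-centred acquisition the scan assumes:
#' the frame must contain the full analysis region of four optic-disc
#' diameters around the disc centre.
#'
#' @param image_size square frame side, pixels.  Must exceed
#'   `2 * od_diameter` so the 4 x D_OD region of interest fits.
#' @param od_diameter optic-disc diameter, pixels.
#' @param n_trunks number of primary vessels leaving the disc (0 allowed).
#' @param branch_prob probability of bifurcation per 1-pixel growth step,
#'   in `[0, 1]`.  This is the main vessel-complexity control.
#' @param width0 trunk half-width (Gaussian cross-section sigma), pixels.
#' @param width_decay multiplicative calibre factor per branching
#'   generation, in `(0, 1)`.
#' @param tortuosity standard deviation of the angular jitter per growth
#'   step, degrees.
#' @param contrast vessel-to-background intensity gap on the `[0, 1]`
#'   intensity scale.
#' @param noise_sd standard deviation of the additive Gaussian pixel noise.
#' @param seed integer RNG seed; identical parameters and seed give a
#'   bit-identical image.
#' @return Object of class `fundus_synth_params` (a validated list).
#' @export
fundus_synth_params <- function(image_size = 400, od_diameter = 100,
                                n_trunks = 6, branch_prob = 0.05,
                                width0 = 2.5, width_decay = 0.8,
                                tortuosity = 6, contrast = 0.45,
                                noise_sd = 0.02, seed = 1) {
  if (branch_prob < 0 || branch_prob > 1) stop("`branch_prob` must be in [0, 1]")
  if (width_decay <= 0 || width_decay >= 1) stop("`width_decay` must be in (0, 1)")
  if (contrast < 0 || contrast > 1) stop("`contrast` must be in [0, 1]")
  if (image_size <= 2 * od_diameter)
    stop("`image_size` must exceed 2 * od_diameter so the 4 x D_OD ROI fits")
  if (n_trunks < 0 || n_trunks != round(n_trunks)) stop("`n_trunks` must be a nonnegative integer")
  structure(list(image_size = image_size, od_diameter = od_diameter,
                 n_trunks = n_trunks, branch_prob = branch_prob,
                 width0 = width0, width_decay = width_decay,
                 tortuosity = tortuosity, contrast = contrast,
                 noise_sd = noise_sd, seed = seed),
            class = "fundus_synth_params")
}

#' Synthetic optic-disc-centred fundus image
#'
#' Draws a greyscale image emulating the green channel of an OD-centred
#' fundus photograph: a brighter disc at the frame centre, vessels grown as
#' stochastic branching random walks that start on the disc boundary and
#' head radially outward, rendered darker than the background with Gaussian
#' cross-sections of generation-decaying width, over a mild illumination
#' gradient with additive noise.  Pixel values are quantized to 8-bit
#' levels (multiples of 1/255) so PNG round-trips are exact.
#'
#' @param params a [fundus_synth_params()] object.
#' @return A list of class `synthetic_fundus` with elements `image`
#'   (numeric matrix in `[0, 1]`), `od` (an [od_annotation()] at the frame
#'   centre), `trunk_seeds` (data frame of vessel starting points on the
#'   disc boundary), `vessel_map` (the noise-free rendered tube profile in
#'   `[0, 1]` — ground truth for validation) and `params`.
#' @export
gen_synthetic_fundus <- function(params) {
  stopifnot(inherits(params, "fundus_synth_params"))
  p <- params
  s <- p$image_size
  c0 <- (s - 1) / 2
  r_od <- p$od_diameter / 2
  od <- od_annotation(c0, c0, p$od_diameter)

  out <- with_seed(p$seed, {
    pts <- grow_vessel_tree(p, c0, r_od)
    vm <- render_vessel_map(pts$points, s)
    xg <- matrix(rep(0:(s - 1), each = s) / (s - 1), s, s)
    yg <- matrix(rep(0:(s - 1), times = s) / (s - 1), s, s)
    bg <- 0.55 + 0.04 * (xg + yg - 1)               # illumination gradient
    rr <- sqrt((xg * (s - 1) - c0)^2 + (yg * (s - 1) - c0)^2)
    od_bump <- 0.25 / (1 + exp((rr - r_od) / 1.5))  # soft-edged bright disc
    img <- bg + od_bump - p$contrast * vm
    if (p$noise_sd > 0) img <- img + matrix(rnorm(s * s, sd = p$noise_sd), s, s)
    img <- pmin(pmax(img, 0), 1)
    list(image = round(img * 255) / 255, seeds = pts$seeds, vm = vm)
  })
  structure(list(image = out$image, od = od, trunk_seeds = out$seeds,
                 vessel_map = out$vm, params = p),
            class = "synthetic_fundus")
}

## grow the branching random-walk tree; returns step points (x, y, width)
grow_vessel_tree <- function(p, c0, r_od) {
  if (p$n_trunks == 0)
    return(list(points = matrix(numeric(0), 0, 3),
                seeds = data.frame(x = numeric(0), y = numeric(0))))
  tort <- p$tortuosity * pi / 180
  r_max <- 2.05 * p$od_diameter            # grow slightly past the outermost circle
  max_pts <- 60000L
  gen_max <- 8L

  ang0 <- 2 * pi * (seq_len(p$n_trunks) - 1) / p$n_trunks +
    runif(p$n_trunks, -pi / (2 * p$n_trunks), pi / (2 * p$n_trunks))
  seeds <- data.frame(x = c0 + r_od * cos(ang0), y = c0 + r_od * sin(ang0))
  ## branch stack: x, y, heading, half-width, generation
  stack <- lapply(seq_len(p$n_trunks), function(i)
    c(seeds$x[i], seeds$y[i], ang0[i], p$width0, 0))
  xs <- numeric(max_pts); ys <- numeric(max_pts); ws <- numeric(max_pts)
  npt <- 0L
  pull <- 0.08                              # radial bias strength

  while (length(stack) > 0 && npt < max_pts) {
    br <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    x <- br[1]; y <- br[2]; phi <- br[3]; w <- br[4]; g <- br[5]
    if (w < 0.5) next
    repeat {
      rad <- atan2(y - c0, x - c0)
      dphi <- (rad - phi + pi) %% (2 * pi) - pi
      phi <- phi + pull * dphi + rnorm(1, 0, tort)
      x <- x + cos(phi); y <- y + sin(phi)
      r <- sqrt((x - c0)^2 + (y - c0)^2)
      if (r > r_max || x < 1 || y < 1 || x > p$image_size - 2 ||
          y > p$image_size - 2 || npt >= max_pts) break
      npt <- npt + 1L
      xs[npt] <- x; ys[npt] <- y; ws[npt] <- w
      if (g < gen_max && runif(1) < p$branch_prob) {
        d1 <- runif(1, 20, 40) * pi / 180
        d2 <- runif(1, 20, 40) * pi / 180
        wc <- w * p$width_decay
        stack[[length(stack) + 1]] <- c(x, y, phi + d1, wc, g + 1)
        stack[[length(stack) + 1]] <- c(x, y, phi - d2, wc, g + 1)
        break
      }
    }
  }
  list(points = cbind(xs[seq_len(npt)], ys[seq_len(npt)], ws[seq_len(npt)]),
       seeds = seeds)
}

## max-composite Gaussian tube profiles onto an s x s canvas
render_vessel_map <- function(points, s) {
  if (nrow(points) == 0) return(matrix(0, s, s))
  render_tubes_cpp(points, s)
}

#' Synthetic case/control cohort of fundus images
#'
#' Draws labelled images from two parameter settings that may differ only
#' in vessel-complexity fields (`branch_prob`, `n_trunks`): the case/control
#' contrast is carried by complexity alone, never by image contrast or
#' noise, which isolates the effect the circular fractal dimension is meant
#' to measure.  Per-image seeds are derived from `seed` via
#' [derive_seed()].
#'
#' @param n_case,n_control group sizes, each at least 2.
#' @param params_case,params_control [fundus_synth_params()] for each arm
#'   (their `seed` fields are ignored in favour of derived seeds).
#' @param seed master seed for the cohort.
#' @return Object of class `synth_cohort`: list with `images` (named list
#'   of `synthetic_fundus`), `labels` (named character vector,
#'   `"case"`/`"control"`), the two parameter sets and `seed`.
#' @export
gen_cohort <- function(n_case, n_control, params_case, params_control, seed) {
  stopifnot(inherits(params_case, "fundus_synth_params"),
            inherits(params_control, "fundus_synth_params"))
  if (n_case < 2 || n_control < 2) stop("each arm needs at least 2 images")
  fixed <- setdiff(names(params_case), c("branch_prob", "n_trunks", "seed"))
  same <- vapply(fixed, function(f)
    identical(params_case[[f]], params_control[[f]]), logical(1))
  if (!all(same))
    stop("case and control parameters may differ only in complexity fields ",
         "(branch_prob, n_trunks); they also differ in: ",
         paste(fixed[!same], collapse = ", "))
  ids <- c(sprintf("case_%03d", seq_len(n_case)),
           sprintf("control_%03d", seq_len(n_control)))
  grp <- c(rep("case", n_case), rep("control", n_control))
  images <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    p <- if (grp[i] == "case") params_case else params_control
    p$seed <- derive_seed(seed, i, stream = 0L)
    images[[i]] <- gen_synthetic_fundus(p)
  }
  names(images) <- ids
  names(grp) <- ids
  structure(list(images = images, labels = grp, params_case = params_case,
                 params_control = params_control, seed = seed),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("Synthetic fundus cohort: %d case, %d control (%dx%d px, D_OD = %g)\n",
              sum(x$labels == "case"), sum(x$labels == "control"),
              x$params_case$image_size, x$params_case$image_size,
              x$params_case$od_diameter))
  invisible(x)
}

#' Write or read a synthetic cohort on disk
#'
#' Images go to 8-bit greyscale PNGs, optic-disc annotations to
#' `annotations.csv` (`image_id, od_cx, od_cy, od_d`) and group labels to
#' `labels.csv` (`image_id, group`).  Because generated images are
#' quantized to 8-bit levels, the round-trip is lossless.
#'
#' @param cohort a `synth_cohort` object.
#' @param dir directory (created if missing).
#' @return `read_cohort` returns a list with `images` (named list of
#'   matrices), `annotations` (named list of [od_annotation()]) and
#'   `labels` (named character vector).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$images))
    png::writePNG(cohort$images[[id]]$image, file.path(dir, paste0(id, ".png")))
  write_od_annotations(lapply(cohort$images, `[[`, "od"),
                       file.path(dir, "annotations.csv"))
  write.csv(data.frame(image_id = names(cohort$labels),
                       group = unname(cohort$labels),
                       stringsAsFactors = FALSE),
            file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  ann <- read_od_annotations(file.path(dir, "annotations.csv"))
  lab <- read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  labels <- stats::setNames(lab$group, lab$image_id)
  images <- lapply(names(ann), function(id) {
    img <- png::readPNG(file.path(dir, paste0(id, ".png")))
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  })
  names(images) <- names(ann)
  list(images = images, annotations = ann, labels = labels)
}
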