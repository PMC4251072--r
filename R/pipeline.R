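#' Pipeline run configuration
#'
#' Bundles the parameters of every stage — preprocessing, enhancement,
#' scanning, fractal estimation, statistics — plus the master seed from
#' which all per-image random streams are derived (see [derive_seed()]).
#' Configurations serialize to YAML and round-trip identically.
#'
#' @param roi_factor,target_side preprocessing, see [preprocess_fundus()].
#' @param enhance_params a [gabor_bank_params()] object.
#' @param n_fit mixture-fit subsample size, see [posterior_image()].
#' @param zones a [zone_spec()].
#' @param k_max Higuchi delay cap, see [higuchi_fd()].
#' @param methods subset of `c("fdc", "sfd", "bc")` to compute.
#' @param skeletonize passed to [binarize_for_bc()].
#' @param confidence level for the report's Mann-Whitney intervals.
#' @param seed master seed.
#' @return Object of class `run_config`.
#' @export
run_config <- function(roi_factor = 4, target_side = 400,
                       enhance_params = gabor_bank_params(), n_fit = 2000,
                       zones = zone_spec(), k_max = 8,
                       methods = c("fdc", "sfd", "bc"), skeletonize = TRUE,
                       confidence = 0.95, seed = 1) {
  methods <- match.arg(methods, c("fdc", "sfd", "bc"), several.ok = TRUE)
  structure(list(roi_factor = roi_factor, target_side = target_side,
                 enhance_params = enhance_params, n_fit = n_fit,
                 zones = zones, k_max = k_max, methods = methods,
                 skeletonize = skeletonize, confidence = confidence,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write or read a run configuration (YAML)
#'
#' @param config a [run_config()] object.
#' @param path file path.
#' @return `read_run_config` returns a `run_config` identical to the one
#'   written.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$enhance_params <- unclass(x$enhance_params)
  x$zones <- list(bounds = c(config$zones$lo, config$zones$hi[nrow(config$zones)]),
                  labels = config$zones$zone)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(
    roi_factor = x$roi_factor, target_side = x$target_side,
    enhance_params = do.call(gabor_bank_params, x$enhance_params),
    n_fit = x$n_fit,
    zones = zone_spec(x$zones$bounds, x$zones$labels),
    k_max = x$k_max, methods = x$methods, skeletonize = x$skeletonize,
    confidence = x$confidence, seed = x$seed)
}

#' Run the full pipeline on a single image
#'
#' Preprocessing (inverted green, ROI crop, downsample), Gabor/mixture
#' vessel enhancement, circular scanning with per-zone Higuchi FD, and the
#' spectral and box-counting comparators.  Reruns with identical inputs,
#' configuration and seed give identical records.
#'
#' @param image greyscale matrix, RGB array, or path to a PNG file.
#' @param od an [od_annotation()] in input-image coordinates.
#' @param config a [run_config()].
#' @param image_seed integer stream index for this image (used to derive
#'   the mixture-fit seed from the master seed); by default derived from
#'   `image_id`.
#' @param image_id identifier recorded in the output.
#' @return A list of class `fd_record`: `image_id`, `fdc` (the full
#'   [fdc()] object), `zone_means`, `sfd`, `bc`, and `meta` (config hash,
#'   package version, skip diagnostics).
#' @export
run_single <- function(image, od, config = run_config(),
                       image_id = "image", image_seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(image)) {
    image <- png::readPNG(image)
    if (length(dim(image)) == 3 && dim(image)[3] < 3) image <- image[, , 1]
  }
  if (is.null(image_seed))
    image_seed <- sum(utf8ToInt(image_id)) %% 4096
  fit_seed <- derive_seed(config$seed, image_seed, stream = 1L)

  wi <- preprocess_fundus(image, od, roi_factor = config$roi_factor,
                          target_side = config$target_side)
  post <- enhance_vessels(wi, params = config$enhance_params,
                          seed = fit_seed, n_fit = config$n_fit)
  out <- list(image_id = image_id, fdc = NULL, zone_means = NULL,
              sfd = NULL, bc = NULL,
              meta = list(config_hash = config_hash(unclass(config)),
                          version = as.character(packageVersion("retfdc")),
                          fit_seed = fit_seed))
  if ("fdc" %in% config$methods) {
    f <- withCallingHandlers(
      fdc(post, zones = config$zones, k_max = config$k_max),
      warning = function(w) invokeRestart("muffleWarning"))
    out$fdc <- f
    out$zone_means <- f$zone_means
    out$meta$n_skipped_circles <- f$n_skipped
  }
  if ("sfd" %in% config$methods) out$sfd <- spectral_fd(post)$value
  if ("bc" %in% config$methods)
    out$bc <- box_counting_fd(
      binarize_for_bc(post, skeletonize = config$skeletonize))$value
  class(out) <- "fd_record"
  out
}

#' @export
print.fd_record <- function(x, ...) {
  cat("FD record for", x$image_id, "\n")
  if (!is.null(x$zone_means)) {
    cat("  FDC: "); print(round(x$zone_means, 4))
  }
  if (!is.null(x$sfd)) cat(sprintf("  SFD: %.4f\n", x$sfd))
  if (!is.null(x$bc)) cat(sprintf("  BC:  %.4f\n", x$bc))
  invisible(x)
}

#' Run the pipeline over a labelled cohort
#'
#' Processes every image of a manifest (or an in-memory [gen_cohort()]
#' object), assembles the long-format FD table, and produces the
#' case/control rank-test report.  Per-image failures are logged and
#' skipped; processing order does not affect the result (per-image seeds
#' derive from subject ids, not row order).
#'
#' @param x a `synth_cohort`, or a data frame manifest with columns
#'   `image_path`, `od_cx`, `od_cy`, `od_d`, `group` and optionally
#'   `subject_id`.
#' @param config a [run_config()].
#' @param progress print one line per image.
#' @return Object of class `fd_cohort`: list with `fd_table` (long data
#'   frame: subject_id, group, method, zone, fd_value), `report` (a
#'   [cohort_report()]), `failures` (character vector of failed ids) and
#'   `meta`.
#' @export
run_cohort <- function(x, config = run_config(), progress = FALSE) {
  if (inherits(x, "synth_cohort")) {
    ids <- names(x$images)
    getter <- function(id) list(image = x$images[[id]]$image,
                                od = x$images[[id]]$od)
    groups <- x$labels
  } else {
    stopifnot(is.data.frame(x))
    ids <- if ("subject_id" %in% names(x)) x$subject_id
           else sub("\\.png$", "", basename(x$image_path))
    rownames(x) <- ids
    getter <- function(id) list(
      image = x[id, "image_path"],
      od = od_annotation(x[id, "od_cx"], x[id, "od_cy"], x[id, "od_d"]))
    groups <- stats::setNames(x$group, ids)
  }
  ord <- sort(ids)
  records <- list(); failures <- character()
  for (id in ord) {
    rec <- tryCatch({
      inp <- getter(id)
      run_single(inp$image, inp$od, config, image_id = id,
                 image_seed = sum(utf8ToInt(id)) %% 4096)
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      message("image ", id, " failed: ", conditionMessage(rec))
      failures <- c(failures, id)
    } else {
      records[[id]] <- rec
      if (progress) cat(sprintf("  %s done\n", id))
    }
  }
  fd_table <- do.call(rbind, lapply(names(records), function(id) {
    r <- records[[id]]
    rows <- list()
    if (!is.null(r$zone_means))
      rows$fdc <- data.frame(subject_id = id, group = unname(groups[id]),
                             method = "FDC", zone = names(r$zone_means),
                             fd_value = unname(r$zone_means))
    if (!is.null(r$sfd))
      rows$sfd <- data.frame(subject_id = id, group = unname(groups[id]),
                             method = "SFD", zone = "ABC", fd_value = r$sfd)
    if (!is.null(r$bc))
      rows$bc <- data.frame(subject_id = id, group = unname(groups[id]),
                            method = "BC", zone = "ABC", fd_value = r$bc)
    do.call(rbind, rows)
  }))
  rownames(fd_table) <- NULL
  report <- cohort_report(fd_table, confidence = config$confidence)
  structure(list(fd_table = fd_table, report = report, failures = failures,
                 meta = list(config_hash = config_hash(unclass(config)),
                             version = as.character(packageVersion("retfdc")),
                             n_failed = length(failures))),
            class = "fd_cohort")
}

#' @export
print.fd_cohort <- function(x, ...) {
  cat(sprintf("Cohort run: %d subjects (%d failed)\n",
              length(unique(x$fd_table$subject_id)), length(x$failures)))
  print(x$report)
  invisible(x)
}
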