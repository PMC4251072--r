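#' Optic-disc annotation
#'
#' Records the manually graded optic-disc centre and diameter that anchor
#' all scan geometry.  Coordinates are 0-based pixel-centre values.
#'
#' @param cx,cy optic-disc centre, pixels.
#' @param d_od optic-disc diameter, pixels (positive).
#' @return Object of class `od_annotation`.
#' @export
od_annotation <- function(cx, cy, d_od) {
  if (!is.finite(d_od) || d_od <= 0) stop("`d_od` must be positive")
  if (!is.finite(cx) || !is.finite(cy)) stop("centre coordinates must be finite")
  structure(list(cx = cx, cy = cy, d_od = d_od), class = "od_annotation")
}

#' @export
print.od_annotation <- function(x, ...) {
  cat(sprintf("Optic disc: centre (%.2f, %.2f), diameter %.2f px\n",
              x$cx, x$cy, x$d_od))
  invisible(x)
}

#' Read or write optic-disc annotation tables
#'
#' CSV columns: `image_id, od_cx, od_cy, od_d` (pixels, 0-based
#' pixel-centre coordinates).
#'
#' @param annotations named list of [od_annotation()] objects (names are
#'   image ids).
#' @param path CSV file path.
#' @return `read_od_annotations` returns a named list of `od_annotation`.
#' @export
write_od_annotations <- function(annotations, path) {
  df <- data.frame(
    image_id = names(annotations),
    od_cx = vapply(annotations, `[[`, numeric(1), "cx"),
    od_cy = vapply(annotations, `[[`, numeric(1), "cy"),
    od_d = vapply(annotations, `[[`, numeric(1), "d_od"),
    stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_od_annotations
#' @export
read_od_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "od_cx", "od_cy", "od_d")
  if (!all(need %in% names(df))) stop("annotation CSV must have columns ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    od_annotation(df$od_cx[i], df$od_cy[i], df$od_d[i]))
  names(out) <- df$image_id
  out
}
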