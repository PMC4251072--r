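#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the R random seed, evaluates `code`, and restores the caller's RNG
#' state afterwards, so seeded generators do not disturb the global stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a master seed
#'
#' All random streams in the package descend from a single master seed via
#' this splitting rule: `(master * 1009 + index * 97 + stream) mod (2^31 - 1)`.
#' `index` distinguishes items (e.g. images in a cohort), `stream`
#' distinguishes purposes (0 = synthesis, 1 = model fitting).
#'
#' @param master integer master seed.
#' @param index non-negative integer item index.
#' @param stream non-negative integer purpose offset.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index = 0L, stream = 0L) {
  as.integer((as.double(master) %% 2147483647 * 1009 +
                as.double(index) * 97 + as.double(stream)) %% 2147483647)
}

#' Clamped bilinear interpolation of image values
#'
#' Samples a greyscale image at fractional 0-based pixel-centre coordinates.
#' Coordinates within half a pixel of the frame edge are clamped to the edge
#' (border replication); exact for planar functions in the interior.
#'
#' @param img numeric matrix, `img[y + 1, x + 1]`.
#' @param x,y numeric vectors of equal length, 0-based coordinates.
#' @return Numeric vector of interpolated values.
#' @export
bilinear_sample <- function(img, x, y) {
  ny <- nrow(img); nx <- ncol(img)
  x <- pmin(pmax(x, 0), nx - 1)
  y <- pmin(pmax(y, 0), ny - 1)
  x0 <- pmin(floor(x), nx - 2); x1 <- x0 + 1
  y0 <- pmin(floor(y), ny - 2); y1 <- y0 + 1
  fx <- x - x0; fy <- y - y0
  i00 <- y0 + 1 + ny * x0; i10 <- y1 + 1 + ny * x0
  i01 <- y0 + 1 + ny * x1; i11 <- y1 + 1 + ny * x1
  (1 - fx) * ((1 - fy) * img[i00] + fy * img[i10]) +
    fx * ((1 - fy) * img[i01] + fy * img[i11])
}

## least-squares slope of y on x (internal, avoids lm() overhead)
ls_slope <- function(x, y) {
  xm <- x - mean(x)
  sum(xm * y) / sum(xm * xm)
}

## short deterministic hash of an R object (config provenance records)
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  ## serialize() headers embed the R version; drop them for stability
  raw <- raw[-seq_len(14)]
  v <- as.integer(raw)
  h1 <- 5381; h2 <- 52711
  for (b in v) {
    h1 <- (h1 * 33 + b) %% 4294967291
    h2 <- (h2 * 17 + b) %% 4294967279
  }
  sprintf("%08x%08x", as.integer(h1 %% 2147483647), as.integer(h2 %% 2147483647))
}
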