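#' Higuchi's fractal dimension of a 1D series
#'
#' Estimates the fractal dimension of the graph of a series from the
#' scaling of mean curve length with delay.  For delay `k` and offset `m`
#' the curve length is
#' `L_m(k) = [ sum_{i=1..n_m} |X(m + i k) - X(m + (i-1) k)| * (N-1)/(n_m k) ] / k`
#' with `n_m = floor((N - m)/k)`; `L(k)` is the mean of `L_m(k)` over
#' `m = 1..k`, and the FD is minus the slope of `log L(k)` against
#' `log k`.  For a bounded series the estimate is clamped to `[1, 2]`
#' (with a warning when clamping occurs).
#'
#' @param series numeric vector, length at least `4 * k_max`, not constant.
#' @param k_max maximum delay used, default 8.
#' @param fit_range delays entering the regression, default `1:k_max`.
#' @return Fractal dimension in `[1, 2]`, with attribute `"log_lengths"`
#'   (the `log L(k)` diagnostics).
#' @examples
#' higuchi_fd(seq_len(1000))            # straight line: FD 1
#' @export
higuchi_fd <- function(series, k_max = 8, fit_range = seq_len(k_max)) {
  N <- length(series)
  if (k_max < 2) stop("`k_max` must be at least 2")
  if (N < 4 * k_max) stop("series too short: need length >= 4 * k_max")
  if (all(series == series[1])) stop("constant series has undefined Higuchi FD")
  lk <- higuchi_lengths(series, k_max)
  fit_range <- intersect(fit_range, seq_len(k_max))
  if (length(fit_range) < 2) stop("`fit_range` must contain at least 2 delays")
  if (any(!is.finite(lk[fit_range])) || any(lk[fit_range] <= 0))
    stop("degenerate curve lengths (locally constant series)")
  fd <- -ls_slope(log(fit_range), log(lk[fit_range]))
  if (fd < 1 - 1e-9 || fd > 2 + 1e-9)
    warning(sprintf("Higuchi FD %.4f outside [1, 2]; clamped", fd))
  fd <- min(max(fd, 1), 2)
  structure(fd, log_lengths = log(lk))
}

## mean normalized curve length L(k) for k = 1..k_max
higuchi_lengths <- function(x, k_max) {
  N <- length(x)
  vapply(seq_len(k_max), function(k) {
    lm <- vapply(seq_len(k), function(m) {
      idx <- seq.int(m, N, by = k)
      nm <- length(idx) - 1L
      if (nm < 1L) return(NA_real_)
      sum(abs(diff(x[idx]))) * (N - 1) / (nm * k) / k
    }, numeric(1))
    mean(lm, na.rm = TRUE)
  }, numeric(1))
}
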