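#' Kruskal-Wallis rank test with per-group summaries
#'
#' One-way analysis of variance by ranks.  Pooled values are midranked
#' (ties share average ranks); the statistic
#' `H = [12/(N(N+1)) * sum(R_j^2 / n_j) - 3(N+1)]` is divided by the tie
#' correction `1 - sum(t^3 - t)/(N^3 - N)`, and the p-value comes from the
#' chi-square distribution with `groups - 1` degrees of freedom.  Each
#' group also gets its median, average rank, and the z-score
#' `(Rbar_j - (N+1)/2) / sqrt((N+1)(N - n_j)/(12 n_j))`.
#'
#' @param values_by_group named list of numeric vectors, one per group
#'   (at least 2 groups of at least 2 values each).
#' @return Object of class `rank_test`: list with `H`, `df`, `p` and a
#'   `groups` data frame (n, median, avg_rank, z per group).
#' @examples
#' kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))  # H = 3.857
#' @export
kruskal_wallis <- function(values_by_group) {
  g <- length(values_by_group)
  if (g < 2) stop("need at least 2 groups")
  if (is.null(names(values_by_group)))
    names(values_by_group) <- paste0("group", seq_len(g))
  n_j <- lengths(values_by_group)
  if (any(n_j < 2)) stop("every group needs at least 2 values")
  pooled <- unlist(values_by_group, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  grp <- rep(names(values_by_group), n_j)
  rbar <- tapply(r, grp, mean)[names(values_by_group)]
  rsum <- rbar * n_j

  H <- 12 / (N * (N + 1)) * sum(rsum^2 / n_j) - 3 * (N + 1)
  ties <- table(pooled)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr <= 0) {
    warning("all values tied: H undefined, reported as 0")
    H <- 0; p <- 1
    z <- rep(0, g)
  } else {
    H <- H / corr
    p <- pchisq(H, df = g - 1, lower.tail = FALSE)
    z <- (rbar - (N + 1) / 2) / sqrt((N + 1) * (N - n_j) / (12 * n_j))
  }
  groups <- data.frame(group = names(values_by_group), n = as.integer(n_j),
                       median = vapply(values_by_group, median, numeric(1)),
                       avg_rank = as.numeric(rbar), z = as.numeric(z),
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(H = H, df = g - 1, p = p, groups = groups),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, digits = 4, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.*f, df = %d, p = %.*f\n",
              digits, x$H, x$df, digits, x$p))
  print(x$groups, digits = digits + 2)
  invisible(x)
}

#' Mann-Whitney confidence interval for a difference in medians
#'
#' Nonparametric shift estimate between two samples: the Hodges-Lehmann
#' point estimate is the median of all pairwise differences
#' `case_i - control_j`, and the confidence interval endpoints are order
#' statistics of the sorted differences at ranks derived from the
#' Mann-Whitney U distribution (exact via `qwilcox` when
#' `m * n <= exact_limit`, normal approximation otherwise).  The achieved
#' confidence of the exact interval is reported.
#'
#' @param case_values,control_values numeric vectors, each of length
#'   at least 2.
#' @param confidence nominal two-sided level, default 0.95.
#' @param exact_limit largest `m * n` for which the exact U distribution
#'   is used.
#' @return Object of class `mw_ci`: list with `point_estimate`, `ci_low`,
#'   `ci_high`, `confidence` (nominal) and `achieved_confidence`.
#' @examples
#' mann_whitney_ci(c(1, 2), c(3, 4))   # point estimate -2
#' @export
mann_whitney_ci <- function(case_values, control_values, confidence = 0.95,
                            exact_limit = 10000) {
  m <- length(case_values); n <- length(control_values)
  if (m < 2 || n < 2) stop("each sample needs at least 2 values")
  d <- sort(as.vector(outer(case_values, control_values, "-")))
  est <- median(d)
  alpha <- 1 - confidence
  mn <- m * n
  if (mn <= exact_limit) {
    ## largest k with P(U <= k - 1) <= alpha/2 gives d[k] as lower bound
    qu <- qwilcox(alpha / 2, m, n)
    k <- if (pwilcox(qu - 1, m, n) <= alpha / 2) qu else qu - 1
    k <- max(k, 0)
    achieved <- 1 - 2 * pwilcox(k - 1, m, n)
  } else {
    k <- floor(mn / 2 - qnorm(1 - alpha / 2) * sqrt(mn * (m + n + 1) / 12))
    k <- max(k, 0)
    achieved <- confidence
  }
  lo <- if (k >= 1) d[k] else d[1]
  hi <- if (k >= 1) d[mn + 1 - k] else d[mn]
  if (lo == hi && length(unique(d)) == 1)
    warning("all pairwise differences tied: zero-width interval")
  structure(list(point_estimate = est, ci_low = lo, ci_high = hi,
                 confidence = confidence, achieved_confidence = achieved),
            class = "mw_ci")
}

#' @export
print.mw_ci <- function(x, digits = 4, ...) {
  cat(sprintf("Hodges-Lehmann shift %.*f, %.1f%% CI (%.*f, %.*f) [achieved %.1f%%]\n",
              digits, x$point_estimate, 100 * x$confidence,
              digits, x$ci_low, digits, x$ci_high,
              100 * x$achieved_confidence))
  invisible(x)
}

#' Case/control report over methods and zones
#'
#' Runs the tie-corrected Kruskal-Wallis test and the Mann-Whitney
#' confidence interval for every method x zone cell of a long-format FD
#' table, laid out like the usual case/control summary: per-group medians,
#' average ranks and z-scores, the confidence interval for
#' `median(case) - median(control)`, H and p.  Rows are ordered by method,
#' then zone A, B, C, AB, AC, BC, ABC.
#'
#' @param table data frame with columns `subject_id`, `group`
#'   (`"case"`/`"control"`), `method`, `zone`, `fd_value` — one value per
#'   subject x method x zone.
#' @param confidence level for the Mann-Whitney interval.
#' @param correct `"none"` (default: every zone tested at face value) or
#'   `"holm"` for a Holm adjustment of the p-values across rows.
#' @return Object of class `cohort_report`: a data frame with one row per
#'   method x zone.
#' @export
cohort_report <- function(table, confidence = 0.95,
                          correct = c("none", "holm")) {
  correct <- match.arg(correct)
  need <- c("subject_id", "group", "method", "zone", "fd_value")
  if (!all(need %in% names(table)))
    stop("`table` must have columns ", paste(need, collapse = ", "))
  if (!all(table$group %in% c("case", "control")))
    stop("`group` must be \"case\" or \"control\"")

  zone_order <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
  cells <- unique(table[, c("method", "zone")])
  cells <- cells[order(cells$method,
                       match(cells$zone, zone_order, nomatch = 99),
                       cells$zone), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- table[table$method == cells$method[i] & table$zone == cells$zone[i], ]
    dup <- duplicated(sub$subject_id)
    if (any(dup)) stop("duplicate subject values in cell ",
                       cells$method[i], "/", cells$zone[i])
    ca <- sub$fd_value[sub$group == "case"]
    co <- sub$fd_value[sub$group == "control"]
    if (length(ca) < 2 || length(co) < 2 || anyNA(c(ca, co))) {
      message("skipping cell ", cells$method[i], "/", cells$zone[i],
              ": incomplete data")
      next
    }
    kw <- kruskal_wallis(list(control = co, case = ca))
    ci <- mann_whitney_ci(ca, co, confidence = confidence)
    gr <- kw$groups
    rows[[length(rows) + 1]] <- data.frame(
      method = cells$method[i], zone = cells$zone[i],
      n_control = gr$n[1], median_control = gr$median[1],
      avg_rank_control = gr$avg_rank[1], z_control = gr$z[1],
      n_case = gr$n[2], median_case = gr$median[2],
      avg_rank_case = gr$avg_rank[2], z_case = gr$z[2],
      ci_low = ci$ci_low, ci_high = ci$ci_high,
      H = kw$H, p = kw$p, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(method = character(), zone = character())
  if (correct == "holm" && nrow(out)) out$p_adj <- stats::p.adjust(out$p, "holm")
  structure(out, class = c("cohort_report", "data.frame"))
}

#' @export
print.cohort_report <- function(x, digits = 4, ...) {
  cat("Case/control rank tests (Kruskal-Wallis + Mann-Whitney CI)\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  print(df, row.names = FALSE)
  invisible(x)
}
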