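test_that("Kruskal-Wallis matches hand computation and base R", {
  out <- kruskal_wallis(list(control = c(1, 2, 3), case = c(4, 5, 6)))
  expect_equal(out$H, 3.857, tolerance = 5e-4)
  expect_equal(out$groups$avg_rank, c(2, 5))
  expect_equal(sum(out$groups$z), 0, tolerance = 1e-12)

  ## agrees with stats::kruskal.test on tied and untied data
  set.seed(12)
  for (i in 1:10) {
    a <- round(rnorm(7), i %% 3)   # varying tie density
    b <- round(rnorm(9), i %% 3)
    c3 <- round(rnorm(5), i %% 3)
    got <- kruskal_wallis(list(a = a, b = b, c = c3))
    ref <- kruskal.test(list(a, b, c3))
    expect_equal(got$H, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis H agrees with exact permutation for small samples", {
  set.seed(13)
  for (i in 1:5) {
    a <- rnorm(4); b <- rnorm(5)
    got <- kruskal_wallis(list(a = a, b = b))
    expect_equal(got$H, oracle_kw_H(list(a, b)), tolerance = 1e-12)
    ## asymptotic p tracks the exact permutation p for these sizes
    ## (chi-square approximation error at n = 4 + 5 is below 0.08)
    p_exact <- oracle_kw_perm_p(a, b)
    expect_lt(abs(got$p - p_exact), 0.08)
  }
})

test_that("rank test has the stated invariances", {
  set.seed(14)
  a <- rnorm(10); b <- rnorm(12) + 0.8
  base <- kruskal_wallis(list(case = a, control = b))
  ## label swap: H and p unchanged, z flips
  sw <- kruskal_wallis(list(control = b, case = a))
  expect_equal(sw$H, base$H)
  expect_equal(sw$p, base$p)
  expect_equal(sort(sw$groups$z), sort(base$groups$z))
  ## strictly monotone transform of pooled values leaves H unchanged
  tr <- kruskal_wallis(list(case = exp(a), control = exp(b)))
  expect_equal(tr$H, base$H, tolerance = 1e-12)
  ## identical groups: no separation
  same <- kruskal_wallis(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$H, 0, tolerance = 1e-12)
  expect_equal(same$groups$z, c(0, 0), tolerance = 1e-12)
  expect_warning(kruskal_wallis(list(a = c(2, 2), b = c(2, 2))), "tied")
})

test_that("Mann-Whitney interval matches enumeration and base R", {
  out <- mann_whitney_ci(c(1, 2), c(3, 4))
  expect_equal(out$point_estimate, -2)  # median of {-3, -2, -2, -1}

  ## pure shift: point estimate recovers the shift exactly
  set.seed(15)
  x <- rnorm(15)
  expect_equal(mann_whitney_ci(x, x - 0.7)$point_estimate, 0.7)

  ## antisymmetry under sample swap
  a <- rnorm(9); b <- rnorm(11) + 0.5
  f <- mann_whitney_ci(a, b); g <- mann_whitney_ci(b, a)
  expect_equal(g$point_estimate, -f$point_estimate)
  expect_equal(g$ci_low, -f$ci_high)
  expect_equal(g$ci_high, -f$ci_low)

  ## agrees with stats::wilcox.test exact confidence interval
  for (i in 1:5) {
    a <- rnorm(8 + i); b <- rnorm(10) + 0.3
    got <- mann_whitney_ci(a, b)
    ref <- suppressWarnings(wilcox.test(a, b, conf.int = TRUE))
    expect_equal(got$point_estimate, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(c(got$ci_low, got$ci_high), as.vector(ref$conf.int),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("cohort report mirrors the case/control table layout", {
  set.seed(16)
  subj <- sprintf("s%02d", 1:20)
  grp <- rep(c("case", "control"), each = 10)
  tab <- do.call(rbind, lapply(c("A", "B", "C", "AB", "AC", "BC", "ABC"),
    function(z) data.frame(subject_id = subj, group = grp, method = "FDC",
                           zone = z,
                           fd_value = rnorm(20, 1.9, 0.01) -
                             0.01 * (grp == "case"))))
  rep1 <- cohort_report(tab)
  expect_s3_class(rep1, "cohort_report")
  expect_identical(rep1$zone, c("A", "B", "C", "AB", "AC", "BC", "ABC"))
  expect_true(all(rep1$ci_low <= rep1$ci_high))
  expect_true(all(rep1$H >= 0 & rep1$p >= 0 & rep1$p <= 1))
  ## single-cell table gives a single row
  one <- cohort_report(tab[tab$zone == "ABC", ])
  expect_identical(nrow(one), 1L)
  ## optional Holm correction adds adjusted p-values
  reph <- cohort_report(tab, correct = "holm")
  expect_true(all(reph$p_adj >= reph$p))
  ## incomplete cells are skipped with a log message
  bad <- tab[!(tab$zone == "B" & tab$group == "case"), ]
  expect_message(repb <- cohort_report(bad), "skipping")
  expect_false("B" %in% repb$zone)
})

test_that("type-I error and CI coverage are calibrated (reduced replicates)", {
  set.seed(17)
  ## null cohorts: both arms drawn from one distribution
  rej <- mean(replicate(200, {
    kruskal_wallis(list(a = rnorm(20, 1.98, 0.01),
                        b = rnorm(20, 1.98, 0.01)))$p < 0.05
  }))
  expect_gte(rej, 0.025); expect_lte(rej, 0.08)

  ## shift-model coverage of the 95% interval
  cover <- mean(replicate(400, {
    ci <- mann_whitney_ci(rnorm(25) + 0.4, rnorm(25))
    ci$ci_low <= 0.4 && 0.4 <= ci$ci_high
  }))
  expect_gte(cover, 0.92); expect_lte(cover, 0.98)
})
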