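test_that("zone means satisfy the exact averaging identities", {
  post <- noise_posterior(seed = 6, side = 200, d_od = 50)
  fit <- fdc(post)
  per <- fit$per_circle
  expect_identical(nrow(per), 75L)
  expect_identical(fit$n_skipped, 0L)

  ## every combination mean equals the mean over its constituent circles
  for (combo in names(fit$zone_means)) {
    zs <- strsplit(combo, "")[[1]]
    expect_equal(fit$zone_means[[combo]],
                 mean(per$fd[per$zone %in% zs]), tolerance = 1e-14)
  }
  ## equal circle counts: pairwise means are simple averages
  zm <- fit$zone_means
  expect_equal(zm[["AB"]], (zm[["A"]] + zm[["B"]]) / 2, tolerance = 1e-12)
  expect_equal(zm[["AC"]], (zm[["A"]] + zm[["C"]]) / 2, tolerance = 1e-12)
  expect_equal(zm[["BC"]], (zm[["B"]] + zm[["C"]]) / 2, tolerance = 1e-12)
  expect_equal(zm[["ABC"]], mean(c(zm[["A"]], zm[["B"]], zm[["C"]])),
               tolerance = 1e-12)
  ## the grand mean lies between the zone extremes
  expect_gte(zm[["ABC"]], min(zm[c("A", "B", "C")]))
  expect_lte(zm[["ABC"]], max(zm[c("A", "B", "C")]))
})

test_that("identical profiles give every zone the same FD", {
  set.seed(7)
  base <- rnorm(400)
  od <- od_annotation(99.5, 99.5, 50)
  ## the same fixed profile on every circle forces equal per-circle FDs
  profiles <- lapply(circle_radii(od), function(r)
    structure(list(radius = r, zone = assign_zone(r, od), samples = base),
              class = "circle_profile"))
  scan <- structure(list(profiles = profiles, od = od, zones = zone_spec()),
                    class = "circle_scan")
  fit <- fdc(scan)
  f <- as.numeric(suppressWarnings(higuchi_fd(base)))
  expect_true(all(abs(fit$zone_means - f) < 1e-14))
})

test_that("denser branching yields higher circular FD", {
  ## pipeline monotonicity at reduced size: branch_prob 0.02 vs 0.10
  fds <- vapply(c(0.02, 0.10), function(bp) {
    mean(vapply(1:5, function(s) {
      sf <- small_fundus(seed = 100 + s, branch_prob = bp)
      wi <- preprocess_fundus(sf$image, sf$od, target_side = 200)
      post <- enhance_vessels(wi, seed = 1, n_fit = 1500)
      suppressWarnings(fdc(post))$zone_means[["ABC"]]
    }, numeric(1)))
  }, numeric(1))
  expect_gt(fds[2], fds[1])
})

test_that("circular scanning is directionally selective for radial structure", {
  ## radial spokes cross the scan circles along their cross-section;
  ## concentric rings run along the scan and leave profiles nearly flat.
  ## Selectivity shows in the captured profile energy (Higuchi FD is
  ## amplitude-invariant, so it cannot grade the sub-quantization residue
  ## that interpolation leaves on along-scan structure).
  side <- 200; c0 <- (side - 1) / 2
  od <- od_annotation(c0, c0, 50)
  xg <- matrix(rep(0:(side - 1), each = side), side, side)
  yg <- matrix(rep(0:(side - 1), times = side), side, side)
  ang <- atan2(yg - c0, xg - c0)
  rr <- sqrt((xg - c0)^2 + (yg - c0)^2)
  mean_sd <- function(img) {
    scan <- scan_all(img, od)
    mean(vapply(scan$profiles, function(p) sd(p$samples), numeric(1)))
  }
  spokes <- (sin(24 * ang) > 0.8) * 255          # radial lines
  rings <- (sin(rr * 0.95) > 0.8) * 255          # concentric rings
  expect_gt(mean_sd(spokes), 5 * mean_sd(rings))

  ## and the spoke profiles support a meaningful FD on every circle
  fs <- suppressWarnings(fdc(spokes, od))
  expect_identical(fs$n_skipped, 0L)
  expect_true(all(fs$zone_means > 1 & fs$zone_means < 2))
})

test_that("fdc methods and accessors are coherent", {
  post <- noise_posterior(seed = 8, side = 200, d_od = 50)
  fit <- fdc(post)
  expect_s3_class(fit, "fdc")
  expect_identical(coef(fit), fit$zone_means)
  expect_named(coef(fit), c("A", "B", "C", "AB", "AC", "BC", "ABC"))
  expect_output(print(fit), "k_max")
  expect_output(summary(fit), "zone A")
  ## matrix + annotation entry point agrees with the posterior entry point
  fit2 <- fdc(post$pixels, post$od)
  expect_identical(fit2$zone_means, fit$zone_means)
})
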