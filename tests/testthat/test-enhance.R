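test_that("Gabor response rejects DC and selects matched orientation", {
  ## constant image: admissible (near zero-mean) wavelet gives ~0 response
  const <- matrix(100, 64, 64)
  r <- gabor_response(const, scale = 4, angle = 0)
  expect_lt(max(r) / 100, 0.02)

  ## bright vertical line responds most at the aligned orientation
  img <- matrix(0, 64, 64)
  img[, 32] <- 1
  resp <- vapply(c(0, 30, 60, 90, 120, 150), function(a)
    max(gabor_response(img, scale = 2, angle = a)), numeric(1))
  expect_identical(which.max(resp), 4L)   # 90 degrees: line along y

  ## and at a matching scale the aligned response dominates a far scale
  expect_gt(max(gabor_response(img, 2, 90)), max(gabor_response(img, 8, 90)))
})

test_that("frequency-domain response matches direct spatial convolution", {
  set.seed(7)
  img <- matrix(rnorm(64 * 64), 64, 64)
  px <- c(20, 40, 31); py <- c(25, 10, 33)
  for (ang in c(0, 40, 110)) {
    full <- gabor_response(img, scale = 2.5, angle = ang)
    direct <- oracle_gabor_at(img, scale = 2.5, angle = ang, px, py)
    got <- full[cbind(py + 1, px + 1)]
    expect_equal(got, direct, tolerance = 1e-6)
  }
})

test_that("response is equivariant under joint 90-degree rotation", {
  set.seed(8)
  img <- matrix(rnorm(96 * 96), 96, 96)
  r0 <- gabor_response(img, scale = 3, angle = 20)
  r90 <- gabor_response(rot90_image(img), scale = 3, angle = (20 + 90) %% 180)
  expect_lt(max(abs(rot90_image(r0) - r90)), 1e-8)
})

test_that("orientation maximum features have the stated structure", {
  set.seed(9)
  img <- matrix(rnorm(64 * 64), 64, 64)
  ## one orientation degenerates to a single response
  p1 <- gabor_bank_params(scales = 3, n_orientations = 1,
                          include_intensity_feature = FALSE)
  f1 <- max_orientation_features(img, p1)
  expect_equal(f1$scale_3, gabor_response(img, 3, 0), tolerance = 1e-12)

  ## max dominates every single orientation pixelwise
  p6 <- gabor_bank_params(scales = 3, n_orientations = 6,
                          include_intensity_feature = FALSE)
  f6 <- max_orientation_features(img, p6)
  for (a in bank_orientations(p6)) {
    expect_true(all(f6$scale_3 >= gabor_response(img, 3, a) - 1e-10))
  }

  ## five scales plus intensity gives six maps
  pfull <- gabor_bank_params()
  ffull <- max_orientation_features(img, pfull)
  expect_length(ffull, 6)
  expect_named(ffull, c(paste0("scale_", 4:8), "intensity"))
})

test_that("feature normalization is affine-invariant and flags degeneracy", {
  set.seed(10)
  f <- matrix(rnorm(32 * 32, mean = 5, sd = 3), 32, 32)
  n1 <- normalize_features(list(a = f))
  expect_lt(abs(mean(n1$a)), 1e-9)
  expect_lt(abs(var(as.vector(n1$a)) - 1), 1e-9)
  n2 <- normalize_features(list(a = 2.5 * f + 7))
  expect_equal(n1$a, n2$a, tolerance = 1e-12)
  expect_warning(out <- normalize_features(list(a = f, b = matrix(1, 32, 32))),
                 "zero-variance")
  expect_named(out, "a")
})

test_that("mixture posterior recovers a two-Gaussian closed form", {
  ## two well-separated intensity populations: posterior saturates per class
  set.seed(11)
  n <- 64
  cls <- matrix(rbinom(n * n, 1, 0.4), n, n)
  img <- matrix(rnorm(n * n, mean = ifelse(cls == 1, 6, 0), sd = 0.7), n, n)
  feats <- normalize_features(list(scale_4 = img))
  post <- posterior_image(feats, od_annotation(31.5, 31.5, 10),
                          seed = 3, n_fit = 2000)
  expect_s3_class(post, "vessel_posterior")
  expect_true(all(post$pixels >= 0 & post$pixels <= 255))
  expect_true(is.integer(post$pixels))
  expect_gt(mean(post$pixels[cls == 1]), 250)
  expect_lt(mean(post$pixels[cls == 0]), 5)

  ## closed-form check: with the fitted parameters, the reported pixel
  ## values equal the analytic two-Gaussian posterior
  fit <- post$fit
  x <- as.vector(feats$scale_4)
  d1 <- fit$pro[1] * stats::dnorm(x, fit$mean[1, 1], sqrt(fit$sigma[1, 1, 1]))
  d2 <- fit$pro[2] * stats::dnorm(x, fit$mean[1, 2], sqrt(fit$sigma[1, 1, 2]))
  vessel <- which.max(fit$mean[1, ])
  pv <- if (vessel == 1) d1 / (d1 + d2) else d2 / (d1 + d2)
  expect_equal(as.vector(post$pixels), as.integer(round(255 * pv)))
})

test_that("posterior margin between vessels and background grows with contrast", {
  ## low-contrast regime: above it the two-class posterior saturates and
  ## the margin plateaus near its ceiling
  margins <- vapply(c(0.02, 0.06, 0.2), function(ct) {
    diffs <- vapply(1:5, function(s) {
      sf <- small_fundus(seed = s, contrast = ct)
      wi <- preprocess_fundus(sf$image, sf$od, target_side = 200)
      post <- enhance_vessels(wi, seed = 5, n_fit = 1500)
      vm <- sf$vessel_map > 0.6          # near-centreline ground truth
      mean(post$pixels[vm]) - mean(post$pixels[!vm])
    }, numeric(1))
    mean(diffs)
  }, numeric(1))
  expect_true(all(diff(margins) > 0))
  expect_gt(margins[3], 100)
})

test_that("enhancement is deterministic given the seed", {
  sf <- small_fundus(seed = 17)
  wi <- preprocess_fundus(sf$image, sf$od, target_side = 200)
  p1 <- enhance_vessels(wi, seed = 9, n_fit = 1000)
  p2 <- enhance_vessels(wi, seed = 9, n_fit = 1000)
  expect_identical(p1$pixels, p2$pixels)
})
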