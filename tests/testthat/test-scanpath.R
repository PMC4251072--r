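test_that("circle radii follow the one-pixel spacing contract", {
  od <- od_annotation(199.5, 199.5, 100)
  r <- circle_radii(od)
  expect_identical(r, 51:200)
  expect_length(r, 150)
  expect_true(all(diff(r) == 1))

  expect_identical(circle_radii(od_annotation(10, 10, 2)), 2:4)
  ## outermost circle must fit in the frame
  expect_error(circle_radii(od_annotation(100, 100, 100), frame_side = 300),
               "exceeds the frame")
  expect_silent(circle_radii(od, frame_side = 400))
})

test_that("zone assignment respects the half-open boundary convention", {
  od <- od_annotation(199.5, 199.5, 100)
  expect_identical(assign_zone(51, od), "A")
  expect_identical(assign_zone(100, od), "A")   # offset exactly 0.5 D_OD
  expect_identical(assign_zone(101, od), "B")
  expect_identical(assign_zone(150, od), "B")
  expect_identical(assign_zone(151, od), "C")
  expect_identical(assign_zone(200, od), "C")   # outer edge: 1.5 D_OD
  expect_error(assign_zone(50, od), "outside")
  expect_error(assign_zone(201, od), "outside")

  ## zones partition the scan: 50 circles per zone for D_OD = 100
  z <- assign_zone(circle_radii(od), od)
  expect_identical(as.vector(table(z)[c("A", "B", "C")]), c(50L, 50L, 50L))
})

test_that("circle sampling is exact for constant and planar images", {
  od <- od_annotation(100, 100, 60)
  const <- matrix(7, 201, 201)
  p <- sample_circle(const, od, 50)
  expect_true(all(p$samples == 7))
  expect_identical(p$zone, "A")

  ## bilinear interpolation is exact for f(x, y) = x
  ramp <- matrix(rep(0:200, each = 201), 201, 201)  # value = x
  p2 <- sample_circle(ramp, od, 50)
  n <- length(p2$samples)
  theta <- 2 * pi * (0:(n - 1)) / n
  expect_equal(p2$samples, 100 + 50 * cos(theta), tolerance = 1e-9)

  ## sample count: one per pixel of arc length
  p3 <- sample_circle(matrix(0:1, 500, 500), od_annotation(249.5, 249.5, 100), 100)
  expect_length(p3$samples, 628)

  expect_error(sample_circle(const, od, 150), "exits")
})

test_that("full scan partitions circles into zones deterministically", {
  post <- noise_posterior(seed = 2, side = 200, d_od = 50)
  scan <- scan_all(post)
  radii <- vapply(scan$profiles, `[[`, numeric(1), "radius")
  zones <- vapply(scan$profiles, `[[`, character(1), "zone")
  expect_identical(radii, as.numeric(26:100))
  expect_identical(as.vector(table(zones)[c("A", "B", "C")]), c(25L, 25L, 25L))
  ## pure function: identical on repeat
  scan2 <- scan_all(post)
  expect_identical(scan$profiles, scan2$profiles)
  ## long-format export
  df <- as.data.frame(scan)
  expect_named(df, c("radius", "zone", "sample_index", "value"))
  expect_identical(nrow(df), sum(vapply(scan$profiles, function(p)
    length(p$samples), numeric(1))) |> as.integer())
})

test_that("rotating the image circularly shifts each profile", {
  img <- gen_power_law_image(3, 200, seed = 4)   # smooth test field
  od <- od_annotation(99.5, 99.5, 50)
  rot <- rot90_image(img)
  for (r in c(30, 60, 90)) {
    p0 <- sample_circle(img, od, r)
    p1 <- sample_circle(rot, od, r)
    n <- length(p0$samples)
    s <- round(n / 4)
    ## rotated profile = original sampled 90 degrees earlier (shift -N/4,
    ## to within one sample of angular discretization)
    shifted <- c(p0$samples[(n - s + 1):n], p0$samples[1:(n - s)])
    expect_gt(cor(p1$samples, shifted), 0.999)
    expect_lt(cor(p1$samples, p0$samples), 0.999)
  }
})
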