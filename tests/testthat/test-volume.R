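test_that("volumes are min-max normalized with degenerate ranges mapping to 0", {
  arr <- array(0, dim = c(4, 4, 3))
  arr[2, 3, 1] <- 255
  vol <- as_volume(arr)
  expect_equal(vol$shape, c(4, 4, 3))
  expect_equal(max(vol$data), 1)
  expect_equal(min(vol$data), 0)

  flat <- as_volume(array(7, dim = c(3, 3, 3)))
  expect_true(all(flat$data == 0))
})

test_that("TIFF write/read round trip reproduces the grid at 8-bit resolution", {
  ph <- cylinder_phantom(radius = 3, shape = c(21, 25, 31))
  f <- withr::local_tempfile(fileext = ".tif")
  write_volume(ph$volume, f)
  back <- load_volume(f)
  expect_equal(back$shape, ph$volume$shape)
  expect_equal(round(back$data * 255), round(ph$volume$data * 255))
})

test_that("a directory of slices and a raw grid with sidecar both load", {
  set.seed(21)
  ref <- array(sample(0:255, 21 * 21 * 9, replace = TRUE) / 255,
               dim = c(21, 21, 9))
  ref[1, 1, 1] <- 0; ref[2, 1, 1] <- 1  # pin the normalization range
  dir <- withr::local_tempdir()
  for (k in seq_len(9))
    tiff::writeTIFF(t(ref[, , k]),
                    file.path(dir, sprintf("slice_%02d.tif", k)),
                    bits.per.sample = 8L)
  vol <- load_volume(dir)
  expect_equal(vol$shape, c(21, 21, 9))
  expect_equal(round(vol$data * 255), round(ref * 255))

  raw <- withr::local_tempfile(fileext = ".raw")
  writeBin(as.integer(round(ref * 255)), raw, size = 1)
  writeLines(c("dims: 21 21 9", "dtype: uint8", "spacing: 1 1 2"),
             paste0(raw, ".meta"))
  vraw <- load_volume(raw)
  expect_equal(vraw$shape, c(21, 21, 9))
  expect_equal(vraw$spacing, c(1, 1, 2))
  expect_equal(round(vraw$data * 255), round(ref * 255))
})

test_that("loading errors are informative", {
  expect_error(load_volume("/nonexistent/file.tif"), "no such file")
  raw <- withr::local_tempfile(fileext = ".raw")
  writeBin(1L, raw, size = 1)
  expect_error(load_volume(raw), "sidecar")
})

test_that("trilinear sampling is exact at voxel centers and midpoints", {
  arr <- array(0, dim = c(5, 5, 5))
  arr[3, 3, 3] <- 255
  vol <- as_volume(arr)
  expect_equal(sample_intensity(vol, c(2, 2, 2)), 1)
  expect_equal(sample_intensity(vol, c(1, 2, 2)), 0)
  # midpoint between voxels valued 0 and 1
  expect_equal(sample_intensity(vol, c(2.5, 2, 2)), 0.5)
  # outside the grid
  expect_equal(sample_intensity(vol, c(-5, 2, 2)), 0)
  expect_error(sample_intensity(vol, c(NA, 1, 1)), "finite")
})

test_that("sampling inside a constant region returns the constant", {
  arr <- array(0, dim = c(11, 11, 11))
  arr[3:9, 3:9, 3:9] <- 200
  vol <- as_volume(arr)
  set.seed(7)
  pts <- matrix(runif(60, 3, 7), ncol = 3)
  expect_equal(sample_intensity(vol, pts), rep(1, 20))
})

test_that("ray casting matches the analytic cylinder", {
  ph <- cylinder_phantom(radius = 5, shape = c(41, 41, 61))
  det <- fixed_detector()
  axis_pt <- c(20, 20, 30)
  perp <- cast_ray(ph$volume, axis_pt, c(1, 0, 0), step = 0.5,
                   max_length = 20, detector = det)
  expect_true(perp$terminated_by_boundary)
  expect_gte(perp$length, 4.5)
  expect_lte(perp$length, 5.5)

  axial <- cast_ray(ph$volume, axis_pt, c(0, 0, 1), step = 1,
                    max_length = 15, detector = det)
  expect_false(axial$terminated_by_boundary)
  expect_equal(axial$length, 15)

  bg <- cast_ray(ph$volume, c(3, 3, 3), c(1, 0, 0), step = 1,
                 max_length = 10, detector = det)
  expect_equal(bg$length, 0)
  expect_true(bg$terminated_by_boundary)
})

test_that("ray length is non-decreasing in max_length and stable under step halving", {
  ph <- cylinder_phantom(radius = 5, shape = c(41, 41, 61))
  det <- fixed_detector()
  dirs <- rbind(c(1, 0, 0), c(0.6, 0.8, 0), c(0, 0.6, 0.8))
  for (i in seq_len(nrow(dirs))) {
    lens <- vapply(c(2, 4, 8, 16), function(L)
      cast_ray(ph$volume, c(20, 20, 30), dirs[i, ], step = 1,
               max_length = L, detector = det)$length, numeric(1))
    expect_true(all(diff(lens) >= 0))
    l1 <- cast_ray(ph$volume, c(20, 20, 30), dirs[i, ], step = 1,
                   max_length = 20, detector = det)$length
    l05 <- cast_ray(ph$volume, c(20, 20, 30), dirs[i, ], step = 0.5,
                    max_length = 20, detector = det)$length
    expect_lte(abs(l1 - l05), 1)
  }
})

test_that("casting from the center of a ball returns the radius in every direction", {
  R <- 8
  ball <- ball_phantom(radius = R)
  det <- fixed_detector()
  set.seed(11)
  for (i in 1:15) {
    d <- rnorm(3)
    d <- d / sqrt(sum(d^2))
    res <- cast_ray(ball$volume, ball$center, d, step = 1,
                    max_length = 20, detector = det)
    expect_true(res$terminated_by_boundary)
    expect_gte(res$length, R - 1)
    expect_lte(res$length, R + 1)
  }
})

test_that("axial supersampling interpolates new slices", {
  ph <- cylinder_phantom(radius = 3, shape = c(21, 21, 31), z0 = 6, z1 = 24)
  f <- withr::local_tempfile(fileext = ".tif")
  write_volume(ph$volume, f)
  vol2 <- load_volume(f, axial_supersample = 2)
  expect_equal(vol2$shape[3], 61)
  # original slices preserved at even positions
  expect_equal(round(vol2$data[, , 5] * 255),
               round(ph$volume$data[, , 3] * 255))
  # interpolated slice is the mean of its neighbors
  expect_equal(vol2$data[, , 4],
               (ph$volume$data[, , 2] + ph$volume$data[, , 3]) / 2,
               tolerance = 1 / 255)
})
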