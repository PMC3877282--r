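test_that("centroid iteration recenters on a binary disc and estimates its radius", {
  ph <- cylinder_phantom(radius = 5, shape = c(41, 41, 41), z0 = 8, z1 = 32)
  det <- fixed_detector()
  res <- refine_centroid_in_plane(ph$volume, c(22, 20, 20), c(0, 0, 1), 5,
                                  detector = det)
  expect_true(res$converged)
  expect_lt(sqrt(sum((res$C[1:2] - 20)^2)), 0.5)
  expect_gte(res$r, 4.5)
  expect_lte(res$r, 5.5)
})

test_that("a centered start is already a fixed point of the centroid iteration", {
  ph <- cylinder_phantom(radius = 5, shape = c(41, 41, 41), z0 = 8, z1 = 32)
  res <- refine_centroid_in_plane(ph$volume, c(20, 20, 20), c(0, 0, 1), 5,
                                  detector = fixed_detector(),
                                  cfg = refine_config(step = 0.25))
  expect_true(res$converged)
  expect_equal(res$iters, 1L)
  expect_equal(res$C[1:2], c(20, 20), tolerance = 0.05)
  expect_lt(abs(res$r - 5), 0.3)
})

test_that("an elliptical cross-section converges to the ellipse center", {
  shape <- c(41, 41, 41)
  arr <- array(0, dim = shape)
  xy <- expand.grid(x = 0:40, y = 0:40)
  inside <- ((xy$x - 20) / 4)^2 + ((xy$y - 20) / 6)^2 <= 1
  sl <- matrix(as.double(inside) * 255, 41, 41)
  for (k in 1:41) arr[, , k] <- sl
  vol <- as_volume(arr)
  res <- refine_centroid_in_plane(vol, c(21.5, 21, 20), c(0, 0, 1), 5,
                                  detector = fixed_detector())
  expect_true(res$converged)
  expect_lt(sqrt(sum((res$C[1:2] - 20)^2)), 0.5)
  expect_gte(res$r, 4)
  expect_lte(res$r, 6)
})

test_that("refinement in open structure flags non-convergence", {
  arr <- array(255, dim = c(31, 31, 31))  # all foreground: no boundary
  vol <- as_volume(arr, normalize = FALSE)
  res <- refine_centroid_in_plane(vol, c(15, 15, 15), c(0, 0, 1), 3,
                                  detector = fixed_detector())
  expect_false(res$converged)
})

test_that("node refinement recovers the axis of straight cylinders, radii 2..10", {
  det <- fixed_detector()
  for (R in c(2, 4, 7, 10)) {
    n <- 4 * R + 21
    c0 <- (n - 1) / 2
    ph <- phantom_tube(shape = c(n, n, 61), start = c(c0, c0, R + 3),
                       end = c(c0, c0, 58 - R), radius = R)
    off <- min(1.5, R / 2)
    tilt <- unit_test(c(sin(10 * pi / 180), 0, cos(10 * pi / 180)))
    res <- refine_node(ph$volume, c(c0 + off, c0, 30), tilt, R,
                       prev_C = c(c0, c0, 22), detector = det)
    expect_true(res$converged)
    expect_lt(sqrt(sum((res$C[1:2] - c0)^2)), 0.5)
    expect_lt(angle_between_test(res$v, c(0, 0, 1)), pi / 36 + 1e-9)
    expect_lte(abs(res$r - R), max(0.5, 0.1 * R))
  }
})

test_that("an on-axis axial start exits after one plane iteration", {
  ph <- cylinder_phantom(radius = 4, shape = c(41, 41, 81))
  res <- refine_node(ph$volume, c(20, 20, 40), c(0, 0, 1), 4,
                     prev_C = c(20, 20, 32), detector = fixed_detector())
  expect_true(res$converged)
  expect_equal(res$plane_iters, 1L)
  expect_lt(angle_between_test(res$v, c(0, 0, 1)), 0.05)
})

test_that("a curved tube is refined onto its arc centerline", {
  # arc of radius 50 about (10, 20) in the xz plane, tube radius 3
  shape <- c(71, 41, 71)
  arr <- array(0, dim = shape)
  ras <- getFromNamespace("rasterize_capsule", "rayburst")
  th <- seq(0.25, 1.05, length.out = 24)
  pts <- cbind(10 + 50 * cos(th), 20, 20 + 50 * sin(th))
  for (i in seq_len(nrow(pts) - 1))
    arr <- ras(arr, pts[i, ], pts[i + 1, ], 3, 3)
  vol <- as_volume(arr)
  mid <- pts[12, ]
  tangent <- unit_test(pts[13, ] - pts[11, ])
  res <- refine_node(vol, mid + c(1, 1, 0), tangent, 3,
                     prev_C = mid - 6 * tangent, detector = fixed_detector())
  expect_true(res$converged)
  expect_gte(res$r, 2.5)
  expect_lte(res$r, 3.5)
  # distance from refined node to the true arc
  d_arc <- abs(sqrt((res$C[1] - 10)^2 + (res$C[3] - 20)^2) - 50)
  expect_lt(sqrt(d_arc^2 + (res$C[2] - 20)^2), 1)
})

test_that("estimated radius tracks the true disc radius across a sweep", {
  det <- fixed_detector()
  for (R in c(2, 3, 5, 8, 10)) {
    n <- 4 * R + 21
    c0 <- (n - 1) / 2
    ph <- phantom_tube(shape = c(n, n, 31), start = c(c0, c0, R + 3),
                       end = c(c0, c0, 28 - R), radius = R)
    res <- refine_centroid_in_plane(ph$volume, c(c0, c0, 15), c(0, 0, 1),
                                    R, detector = det)
    expect_lte(abs(res$r - R), 1)  # within one step of truth
  }
})

test_that("successive centroid displacements shrink on convex sections", {
  ph <- cylinder_phantom(radius = 6, shape = c(41, 41, 41), z0 = 8, z1 = 32)
  det <- fixed_detector()
  ring <- ring_core(32)
  # manually run iterations and record displacements
  C <- c(23, 21, 20)
  disp <- numeric(0)
  for (i in 1:6) {
    res <- refine_centroid_in_plane(ph$volume, C, c(0, 0, 1), 6,
                                    ring = ring, detector = det,
                                    cfg = refine_config(max_centroid_iters = 1))
    disp <- c(disp, sqrt(sum((res$C - C)^2)))
    C <- res$C
  }
  expect_true(all(diff(disp[-1]) <= 1e-6))
})

test_that("refinement is equivariant under axis-aligned rotations", {
  det <- fixed_detector()
  shape <- c(41, 41, 61)
  ph <- cylinder_phantom(radius = 4, shape = shape)
  res_z <- refine_node(ph$volume, c(21.5, 20, 30), c(0, 0, 1), 4,
                       prev_C = c(20, 20, 22), detector = det)
  # same cylinder along x: swap axes of the phantom
  arr_x <- aperm(ph$volume$data, c(3, 2, 1))
  vol_x <- as_volume(arr_x, normalize = FALSE)
  res_x <- refine_node(vol_x, c(30, 20, 21.5), c(1, 0, 0), 4,
                       prev_C = c(22, 20, 20), detector = det)
  expect_equal(res_x$C[c(3, 2, 1)], res_z$C, tolerance = 1e-6)
  expect_equal(res_x$v[c(3, 2, 1)], res_z$v, tolerance = 1e-6)
  expect_equal(res_x$r, res_z$r, tolerance = 1e-6)
})
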