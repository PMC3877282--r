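test_that("hemisphere core has the square-ring population structure", {
  core <- hemisphere_core(M = 7)
  expect_equal(nrow(core$vectors), 169)
  expect_equal(tabulate(core$ring + 1L), c(1, 8, 16, 24, 32, 40, 48))
  expect_lt(max(abs(sqrt(rowSums(core$vectors^2)) - 1)), 1e-9)
  expect_true(all(core$vectors[, 3] >= 0))
  expect_equal(core$vectors[1, ], c(0, 0, 1))
  expect_error(hemisphere_core(M = 1), ">= 2")
})

test_that("core vector count equals the ring-sum oracle for M = 2..12", {
  for (M in 2:12) {
    # independent oracle: brute-force sum over ring populations
    oracle <- sum(vapply(0:(M - 1), function(k) max(1, 8 * k), numeric(1)))
    expect_equal(nrow(hemisphere_core(M)$vectors), oracle)
    expect_equal(oracle, 1 + 4 * M * (M - 1))
  }
})

test_that("grid map is a bijection onto the square grid and round trips", {
  for (M in c(3, 7)) {
    core <- hemisphere_core(M)
    G <- 2 * M - 1
    cells <- cbind(core$gx, core$gy)
    expect_equal(nrow(unique(cells)), G^2)      # every cell hit once
    expect_true(all(cells >= 1 & cells <= G))
    # round trip: vector -> cell -> vector
    idx_of <- matrix(NA_integer_, G, G)
    idx_of[cells] <- seq_len(nrow(cells))
    expect_equal(idx_of[cells], seq_len(nrow(cells)))
    # ring k occupies the Chebyshev-radius-k square ring
    cheb <- pmax(abs(core$gx - M), abs(core$gy - M))
    expect_equal(cheb, core$ring)
  }
})

test_that("anisotropy scaling keeps unit norm, the pole and the equator", {
  iso <- hemisphere_core(7, epsilon_aniso = 1)
  aniso <- hemisphere_core(7, epsilon_aniso = 1.1)
  expect_lt(max(abs(sqrt(rowSums(aniso$vectors^2)) - 1)), 1e-9)
  expect_equal(aniso$vectors[1, ], c(0, 0, 1))
  eq <- aniso$ring == 6
  expect_equal(aniso$vectors[eq, ], iso$vectors[eq, ], tolerance = 1e-12)
  # non-equator, non-pole vectors tilt toward the pole
  mid <- aniso$ring == 3
  expect_true(all(aniso$vectors[mid, 3] > iso$vectors[mid, 3]))
})

test_that("rotate_core applies a rigid rotation preserving the half-space", {
  core <- hemisphere_core(7)
  expect_equal(rotate_core(core, c(0, 0, 1)), core$vectors,
               ignore_attr = TRUE)
  rx <- rotate_core(core, c(1, 0, 0))
  expect_equal(rx[1, ], c(1, 0, 0), tolerance = 1e-12)
  # pairwise angles preserved
  gram0 <- core$vectors %*% t(core$vectors)
  expect_lt(max(abs(rx %*% t(rx) - gram0)), 1e-9)
  set.seed(3)
  for (i in 1:5) {
    v <- rnorm(3)
    v <- v / sqrt(sum(v^2))
    rv <- rotate_core(core, v)
    expect_true(all(rv %*% v >= -1e-9))
  }
  # antipode tie-break is a proper rotation
  rneg <- rotate_core(core, c(0, 0, -1))
  expect_equal(rneg[1, ], c(0, 0, -1), tolerance = 1e-12)
  expect_error(rotate_core(core, c(0, 0, 0)), "non-zero")
})

test_that("ring core has uniform angular spacing and zero sum", {
  expect_error(ring_core(4), ">= 8")
  rc8 <- ring_core(8)
  ang <- atan2(rc8$vectors[, 2], rc8$vectors[, 1])
  expect_equal(diff(ang[1:3]), rep(pi / 4, 2))
  rc <- ring_core(32)
  expect_equal(rc$N, 32)
  d <- rowSums(rc$vectors * rbind(rc$vectors[-1, ], rc$vectors[1, ]))
  expect_equal(d, rep(cos(2 * pi / 32), 32))
  expect_lt(max(abs(colSums(rc$vectors))), 1e-12)
})

test_that("hemisphere sampling sees one cluster on a tube, two at a Y junction", {
  core <- hemisphere_core()
  det <- fixed_detector()
  ph <- cylinder_phantom(radius = 4, shape = c(41, 41, 81))
  hs <- hemisphere_sample(ph$volume, c(20, 20, 40), c(0, 0, 1), 4, core,
                          det, sampling_distance = 3)
  expect_true(hs$valid)
  bd <- detect_branch_directions(hs, core)
  expect_equal(nrow(bd), 1)
  # the cluster contains the center (pole) cell
  expect_equal(hs$grid[core$M, core$M], 1L)
  expect_lt(angle_between_test(bd[1, ], c(0, 0, 1)), pi / 12)

  y <- y_phantom()
  hsy <- hemisphere_sample(y$volume, y$junction - c(0, 0, 2), c(0, 0, 1),
                           y$radius, core, det, sampling_distance = 3)
  bdy <- detect_branch_directions(hsy, core)
  expect_equal(nrow(bdy), 2)
  # each detected direction points at one daughter
  ang1 <- min(acos(pmin(1, bdy %*% y$daughters[1, ])))
  ang2 <- min(acos(pmin(1, bdy %*% y$daughters[2, ])))
  expect_lt(ang1, pi / 6)
  expect_lt(ang2, pi / 6)

  bg <- hemisphere_sample(ph$volume, c(4, 4, 4), c(0, 0, 1), 4, core, det)
  expect_false(bg$valid)
  expect_equal(nrow(detect_branch_directions(bg, core)), 0)
})

test_that("a half-space sampled shallowly leaves every ray inside", {
  shape <- c(41, 41, 41)
  arr <- array(0, dim = shape)
  arr[, , 16:41] <- 255  # foreground where z >= 15
  vol <- as_volume(arr)
  core <- hemisphere_core()
  hs <- hemisphere_sample(vol, c(20, 20, 20), c(0, 0, 1), 3,
                          core, fixed_detector(), sampling_distance = 1.5)
  expect_true(all(hs$state == 1L))
})

test_that("branch count equals component count on random grids (labeling oracle)", {
  skip_if_not_installed("igraph")
  core <- hemisphere_core(7)
  G <- core$grid_size
  # independent component-count oracle via igraph over 8-neighbor edges
  oracle_components <- function(grid) {
    on <- which(grid > 0, arr.ind = TRUE)
    if (nrow(on) == 0) return(0L)
    key <- paste(on[, 1], on[, 2])
    edges <- integer(0)
    for (a in seq_len(nrow(on))) {
      for (dx in -1:1) for (dy in -1:1) {
        if (dx == 0 && dy == 0) next
        nb <- match(paste(on[a, 1] + dx, on[a, 2] + dy), key)
        if (!is.na(nb)) edges <- c(edges, a, nb)
      }
    }
    g <- igraph::make_graph(edges, n = nrow(on), directed = FALSE)
    igraph::components(g)$no
  }
  set.seed(42)
  for (i in 1:8) {
    grid <- matrix(as.integer(runif(G * G) < 0.25), G, G)
    fake <- structure(list(valid = TRUE, grid = grid, frame = diag(3)),
                      class = "hemisphere_sample")
    bd <- detect_branch_directions(fake, core)
    expect_equal(nrow(bd), oracle_components(grid))
  }
})

test_that("the component center is the distance-transform maximum", {
  core <- hemisphere_core(7)
  G <- core$grid_size
  grid <- matrix(0L, G, G)
  # two disjoint 3x3 blocks; centers at (3,3) and (10,10)
  grid[2:4, 2:4] <- 1L
  grid[9:11, 9:11] <- 1L
  fake <- structure(list(valid = TRUE, grid = grid, frame = diag(3)),
                    class = "hemisphere_sample")
  bd <- detect_branch_directions(fake, core)
  expect_equal(nrow(bd), 2)
  idx_of <- matrix(NA_integer_, G, G)
  idx_of[cbind(core$gx, core$gy)] <- seq_along(core$ring)
  want <- core$vectors[c(idx_of[3, 3], idx_of[10, 10]), ]
  got <- bd[order(bd[, 3], decreasing = TRUE), ]
  want <- want[order(want[, 3], decreasing = TRUE), ]
  expect_equal(got, want, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("a symmetric cap about the pole yields the pole direction", {
  core <- hemisphere_core(7)
  G <- core$grid_size
  grid <- matrix(0L, G, G)
  M <- core$M
  cheb <- pmax(abs(row(grid) - M), abs(col(grid) - M))
  grid[cheb <= 2] <- 1L  # rings 0..2 fully on
  fake <- structure(list(valid = TRUE, grid = grid, frame = diag(3)),
                    class = "hemisphere_sample")
  bd <- detect_branch_directions(fake, core)
  expect_equal(nrow(bd), 1)
  expect_lt(angle_between_test(bd[1, ], c(0, 0, 1)), pi / 12)
})
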