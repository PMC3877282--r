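#' Synthetic tube phantom
#'
#' Rasterizes a single capsule (a cylinder with hemispherical caps,
#' optionally tapering linearly between `radius` and `radius_end`) into a
#' binary volume, with exact ground truth. A voxel is foreground when its
#' center lies within the local radius of the segment axis; with the
#' `"gaussian"` intensity model the foreground plateau decays outside the
#' radius with a Gaussian profile of width `sigma`.
#'
#' @param shape grid dimensions, length-3 integer.
#' @param start,end segment endpoints in continuous voxel coordinates.
#' @param radius,radius_end radii in voxels (`>= 1`); `radius_end` defaults
#'   to `radius`.
#' @param intensity_model `"binary"` (default) or `"gaussian"`.
#' @param sigma Gaussian falloff width in voxels (gaussian model only).
#' @param margin required clearance between the tube surface and the grid
#'   boundary (default 2 voxels).
#' @param truth_spacing spacing of ground-truth centerline points (voxels).
#' @return list with `volume` (a `ray_volume`) and `truth` (a
#'   `phantom_truth`: `swc` ground-truth tree, `centerlines`,
#'   `total_length`, `bifurcation_count`, `root`).
#' @export
phantom_tube <- function(shape = c(64, 64, 64), start, end, radius,
                         radius_end = radius,
                         intensity_model = c("binary", "gaussian"),
                         sigma = 1, margin = 2, truth_spacing = 2) {
  intensity_model <- match.arg(intensity_model)
  if (radius < 1 || radius_end < 1)
    stop("phantom radii must be >= 1 voxel", call. = FALSE)
  shape <- as.integer(shape)
  check_segment_margin(start, end, max(radius, radius_end), shape, margin)
  arr <- array(0, dim = shape)
  arr <- rasterize_capsule(arr, start, end, radius, radius_end,
                           intensity_model, sigma)
  seg_len <- vnorm(end - start)
  pts <- polyline_points(start, end, truth_spacing)
  rr <- radius + (radius_end - radius) * seq(0, 1, length.out = nrow(pts))
  swc <- neuron_tree(tibble::tibble(
    id = seq_len(nrow(pts)), type = 3L,
    x = pts[, 1], y = pts[, 2], z = pts[, 3], radius = rr,
    parent = c(-1L, seq_len(nrow(pts) - 1L))))
  truth <- structure(list(
    swc = swc,
    centerlines = list(cbind(pts, radius = rr)),
    total_length = seg_len,
    bifurcation_count = 0L,
    root = as.double(start)), class = "phantom_truth")
  list(volume = as_volume(arr), truth = truth)
}

check_segment_margin <- function(start, end, r, shape, margin) {
  lo <- r + margin
  hi <- shape - 1 - r - margin
  if (any(start < lo) || any(start > hi) || any(end < lo) || any(end > hi))
    stop("segment exits the grid margin (need ", margin,
         " voxels of clearance beyond the tube surface)", call. = FALSE)
}

polyline_points <- function(start, end, spacing) {
  len <- vnorm(end - start)
  n <- max(2L, ceiling(len / spacing) + 1L)
  t <- seq(0, 1, length.out = n)
  cbind(start[1] + t * (end[1] - start[1]),
        start[2] + t * (end[2] - start[2]),
        start[3] + t * (end[3] - start[3]))
}

# Mark voxels within the (tapering) capsule around segment start-end.
# Only the segment's bounding box is visited.
rasterize_capsule <- function(arr, start, end, r0, r1, model = "binary",
                              sigma = 1) {
  shape <- dim(arr)
  rmax <- max(r0, r1)
  pad <- rmax + if (model == "gaussian") 3 * sigma else 0
  lo <- pmax(floor(pmin(start, end) - pad - 1), 0)
  hi <- pmin(ceiling(pmax(start, end) + pad + 1), shape - 1)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  px <- rep(xs, times = ny * nz)
  py <- rep(rep(ys, each = nx), times = nz)
  pz <- rep(zs, each = nx * ny)
  d <- end - start
  L2 <- sum(d^2)
  t <- if (L2 > 0)
    pmin(pmax(((px - start[1]) * d[1] + (py - start[2]) * d[2] +
                 (pz - start[3]) * d[3]) / L2, 0), 1)
  else rep(0, length(px))
  dx <- px - (start[1] + t * d[1])
  dy <- py - (start[2] + t * d[2])
  dz <- pz - (start[3] + t * d[3])
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  r_t <- r0 + t * (r1 - r0)
  val <- if (model == "binary") as.double(dist <= r_t)
         else pmin(1, exp(-pmax(dist - r_t, 0)^2 / (2 * sigma^2)))
  sub <- array(val, dim = c(nx, ny, nz))
  old <- arr[xs + 1, ys + 1, zs + 1]
  arr[xs + 1, ys + 1, zs + 1] <- pmax(old, sub * 255)
  arr
}

#' Synthetic tubular-tree phantom with ground truth
#'
#' Grows a seeded random binary tree of tapering capsules inside the grid
#' and rasterizes it, recording exact ground truth (per-branch centerline
#' polylines, an SWC tree, the total centerline length and the bifurcation
#' count). At each level every branch splits in two: the children leave
#' the parent direction by a polar angle drawn uniformly from
#' `branch_angle` (degrees) at roughly opposite azimuths, child radius is
#' `radius_decay` times the parent radius (floored at 1 voxel), and child
#' length shrinks by `length_decay`. Segments are clipped to keep the tube
#' inside the grid margin; a clipped segment shorter than `min_length` is
#' dropped, and a split with fewer than two surviving children is not
#' counted as a bifurcation. The same seed always reproduces the same
#' phantom bit-exactly.
#'
#' @param shape grid dimensions (default `c(101, 101, 101)`).
#' @param depth number of branching levels (`>= 1`; depth 1 is a single
#'   unbranched trunk).
#' @param trunk_radius trunk radius in voxels.
#' @param radius_decay child/parent radius ratio (default 0.8).
#' @param branch_angle polar branch angle range in degrees
#'   (default `c(25, 40)`).
#' @param trunk_length trunk length in voxels (default 30).
#' @param length_decay child/parent length ratio (default 0.85).
#' @param seed RNG seed controlling tree generation.
#' @param min_length minimum surviving segment length (default 8 voxels).
#' @param margin grid clearance in voxels (default 2).
#' @inheritParams phantom_tube
#' @return list with `volume` and `truth`, as in [phantom_tube()].
#' @export
phantom_tree <- function(shape = c(101, 101, 101), depth = 3,
                         trunk_radius = 4, radius_decay = 0.8,
                         branch_angle = c(25, 40), trunk_length = 30,
                         length_decay = 0.85, seed = 1, min_length = 8,
                         margin = 2, intensity_model = "binary", sigma = 1,
                         truth_spacing = 2) {
  stopifnot(depth >= 1, trunk_radius >= 1)
  shape <- as.integer(shape)
  segs <- withr::with_seed(as.integer(seed), {
    grow_tree(shape, depth, trunk_radius, radius_decay,
              branch_angle * pi / 180, trunk_length, length_decay,
              min_length, margin)
  })
  if (length(segs) == 0L)
    stop("recipe cannot fit in the grid; reduce depth, radius or lengths",
         call. = FALSE)
  arr <- array(0, dim = shape)
  for (s in segs)
    arr <- rasterize_capsule(arr, s$start, s$end, s$r0, s$r1,
                             intensity_model, sigma)
  truth <- build_tree_truth(segs, truth_spacing)
  list(volume = as_volume(arr), truth = truth)
}

grow_tree <- function(shape, depth, r_trunk, decay, angle_range, len0,
                      len_decay, min_length, margin) {
  segs <- list()
  n_bif <- 0L
  safe_clip <- function(start, dir, len, r) {
    lo <- rep(r + margin, 3)
    hi <- shape - 1 - r - margin
    t_max <- len
    for (ax in 1:3) {
      if (dir[ax] > 1e-12) t_max <- min(t_max, (hi[ax] - start[ax]) / dir[ax])
      if (dir[ax] < -1e-12) t_max <- min(t_max, (lo[ax] - start[ax]) / dir[ax])
    }
    max(t_max, 0)
  }
  grow <- function(start, dir, len, r, level, parent_seg) {
    t_max <- safe_clip(start, dir, len, r)
    if (t_max < min_length) return(invisible(NULL))
    end <- start + t_max * dir
    seg_id <- length(segs) + 1L
    segs[[seg_id]] <<- list(start = start, end = end, r0 = r, r1 = r,
                            parent = parent_seg, level = level)
    if (level < depth) {
      az <- runif(1, 0, 2 * pi)
      jit <- runif(1, -pi / 6, pi / 6)
      a1 <- runif(1, angle_range[1], angle_range[2])
      a2 <- runif(1, angle_range[1], angle_range[2])
      r_child <- max(r * decay, 1)
      len_child <- len * len_decay
      b <- plane_basis(dir)
      mk <- function(a, phi)
        unit(cos(a) * dir + sin(a) * (cos(phi) * b$e1 + sin(phi) * b$e2))
      before <- length(segs)
      grow(end, mk(a1, az), len_child, r_child, level + 1L, seg_id)
      n1 <- length(segs) - before
      before2 <- length(segs)
      grow(end, mk(a2, az + pi + jit), len_child, r_child, level + 1L,
           seg_id)
      n2 <- length(segs) - before2
      if (n1 > 0L && n2 > 0L) n_bif <<- n_bif + 1L
    }
    invisible(NULL)
  }
  root <- c(shape[1] / 2, shape[2] / 2, margin + r_trunk + 1)
  tilt <- runif(1, 0, 10 * pi / 180)
  az0 <- runif(1, 0, 2 * pi)
  dir0 <- unit(c(sin(tilt) * cos(az0), sin(tilt) * sin(az0), cos(tilt)))
  grow(root, dir0, len0, r_trunk, 1L, 0L)
  attr(segs, "bifurcation_count") <- n_bif
  segs
}

build_tree_truth <- function(segs, truth_spacing) {
  nodes <- list()
  next_id <- 0L
  end_node_of_seg <- integer(length(segs))
  add_node <- function(p, r, parent) {
    next_id <<- next_id + 1L
    nodes[[next_id]] <<- c(id = next_id, x = p[1], y = p[2], z = p[3],
                           radius = r, parent = parent)
    next_id
  }
  centerlines <- list()
  total_len <- 0
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    pts <- polyline_points(s$start, s$end, truth_spacing)
    centerlines[[i]] <- cbind(pts, radius = s$r0)
    total_len <- total_len + vnorm(s$end - s$start)
    parent <- if (s$parent == 0L) {
      add_node(pts[1, ], s$r0, -1L)
    } else {
      end_node_of_seg[s$parent]
    }
    for (k in 2:nrow(pts))
      parent <- add_node(pts[k, ], s$r0, parent)
    end_node_of_seg[i] <- parent
  }
  m <- do.call(rbind, nodes)
  swc <- neuron_tree(tibble::tibble(
    id = as.integer(m[, "id"]), type = 3L, x = m[, "x"], y = m[, "y"],
    z = m[, "z"], radius = m[, "radius"],
    parent = as.integer(m[, "parent"])))
  structure(list(
    swc = swc,
    centerlines = centerlines,
    total_length = total_len,
    bifurcation_count = attr(segs, "bifurcation_count"),
    root = as.double(segs[[1]]$start)), class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth>", length(x$centerlines), "branch(es),",
      x$bifurcation_count, "bifurcation(s), total length",
      format(x$total_length, digits = 6), "voxels\n")
  invisible(x)
}

#' Add Gaussian noise to a volume
#'
#' Adds i.i.d. Gaussian noise with the given standard deviation on the
#' 8-bit intensity scale, clips to `[0, 255]` and rescales back to
#' `[0, 1]`. Seeded and reproducible.
#'
#' @param vol a `ray_volume`.
#' @param sd noise standard deviation on the 8-bit scale (`>= 0`; the
#'   robustness experiments use 5-30).
#' @param seed RNG seed.
#' @return A new `ray_volume`.
#' @export
add_noise <- function(vol, sd, seed = 1) {
  stopifnot(inherits(vol, "ray_volume"), sd >= 0)
  if (sd == 0) return(vol)
  noisy <- withr::with_seed(as.integer(seed), {
    v <- vol$data * 255 + rnorm(length(vol$data), 0, sd)
    pmin(pmax(v, 0), 255) / 255
  })
  as_volume(array(noisy, dim = vol$shape), spacing = vol$spacing,
            normalize = FALSE)
}

#' Fixed phantom regression suite
#'
#' Five seeded tree phantoms (101 cubed, depths 3-4, trunk radii 3-6)
#' used throughout the package's end-to-end validation. The recipes are
#' fixed; only the generator seed varies with `seeds`.
#'
#' @param seeds integer seeds, one phantom per seed (default `1:5`).
#' @return list of `phantom_tree()` results.
#' @export
phantom_suite <- function(seeds = 1:5) {
  depths <- c(3, 4, 3, 4, 3)
  radii <- c(4, 5, 3, 6, 4)
  lapply(seq_along(seeds), function(i) {
    k <- ((i - 1L) %% 5L) + 1L
    phantom_tree(shape = c(101, 101, 101), depth = depths[k],
                 trunk_radius = radii[k], seed = seeds[i])
  })
}
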