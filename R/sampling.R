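#' Hemispherical sampling core
#'
#' Precomputes an approximately uniform set of unit vectors on the forward
#' hemisphere (pole along `+z`), organized for branch detection. The
#' hemisphere is divided into `M` inclination rings with equal angular
#' spacing, `theta_k = k * (pi/2) / (M - 1)` for `k = 0 .. M-1` (pole
#' through equator). Ring `k` carries `max(1, 8k)` azimuth slots at equal
#' intervals, so the ring populations are 1, 8, 16, 24, ...: exactly the
#' cell counts of concentric square rings, which gives a bijection between
#' the hemisphere vectors and the cells of a `(2M-1) x (2M-1)` square grid
#' (each inclination circle maps to its circumscribed square). On each
#' square ring the azimuthal order starts at the `+x` cell and proceeds
#' counterclockwise, matching the azimuth angle.
#'
#' An optional anisotropy coefficient `epsilon_aniso >= 1` scales the `z`
#' component of every vector before renormalization, compensating for lower
#' axial image resolution; equator vectors (`z = 0`) are unaffected.
#'
#' @param M inclination division count (`>= 2`, default 7, giving 169
#'   vectors).
#' @param epsilon_aniso anisotropy coefficient (`>= 1`; useful range is
#'   about 1.0-1.1).
#' @return A `hemisphere_core`: list with `vectors` (n-by-3 unit rows),
#'   `ring`, `slot`, `gx`, `gy` (1-based square-grid cell per vector), `M`,
#'   `grid_size` and `epsilon_aniso`.
#' @export
hemisphere_core <- function(M = 7, epsilon_aniso = 1) {
  if (!is.numeric(M) || M < 2)
    stop("`M` must be an integer >= 2", call. = FALSE)
  if (epsilon_aniso < 1)
    stop("`epsilon_aniso` must be >= 1", call. = FALSE)
  M <- as.integer(M)
  G <- 2L * M - 1L
  rows <- vector("list", M)
  for (k in 0:(M - 1)) {
    theta <- k * (pi / 2) / (M - 1)
    n_k <- max(1L, 8L * k)
    j <- 0:(n_k - 1L)
    phi <- j * 2 * pi / n_k
    v <- cbind(sin(theta) * cos(phi),
               sin(theta) * sin(phi),
               cos(theta))
    if (epsilon_aniso > 1) {
      v[, 3] <- v[, 3] * epsilon_aniso
      v <- v / sqrt(rowSums(v^2))
    }
    cell <- ring_perimeter_cells(k)
    rows[[k + 1]] <- list(v = v, ring = rep(k, n_k), slot = j,
                          gx = M + cell[, 1], gy = M + cell[, 2])
  }
  core <- list(
    vectors = do.call(rbind, lapply(rows, `[[`, "v")),
    ring = unlist(lapply(rows, `[[`, "ring")),
    slot = unlist(lapply(rows, `[[`, "slot")),
    gx = unlist(lapply(rows, `[[`, "gx")),
    gy = unlist(lapply(rows, `[[`, "gy")),
    M = M, grid_size = G, epsilon_aniso = epsilon_aniso)
  # pole row has exact coordinates
  core$vectors[1, ] <- c(0, 0, 1)
  class(core) <- "hemisphere_core"
  core
}

# Offsets (dx, dy) of the perimeter cells of the (2k+1) x (2k+1) square
# ring, ordered counterclockwise by angle starting at (k, 0); ring 0 is the
# single center cell.
ring_perimeter_cells <- function(k) {
  if (k == 0) return(matrix(c(0L, 0L), 1, 2))
  d <- -k:k
  cells <- rbind(cbind(k, d), cbind(-k, d), cbind(d, k), cbind(d, -k))
  cells <- unique(cells)
  ang <- atan2(cells[, 2], cells[, 1]) %% (2 * pi)
  cells[order(ang), , drop = FALSE]
}

#' @export
print.hemisphere_core <- function(x, ...) {
  cat("<hemisphere_core> M =", x$M, ":", nrow(x$vectors),
      "vectors on a", x$grid_size, "x", x$grid_size, "grid",
      if (x$epsilon_aniso > 1) paste0("(anisotropy ", x$epsilon_aniso, ")"),
      "\n")
  invisible(x)
}

#' Rotate a sampling core to a node direction
#'
#' Applies the minimal rotation taking the canonical pole `(0, 0, 1)` onto
#' `v` to every core vector. `v = (0, 0, 1)` applies the identity;
#' `v = (0, 0, -1)` uses a fixed 180-degree rotation about the x axis.
#'
#' @param core a [hemisphere_core()].
#' @param v unit 3-vector, the node direction.
#' @return n-by-3 matrix of rotated unit vectors.
#' @export
rotate_core <- function(core, v) {
  stopifnot(inherits(core, "hemisphere_core"))
  if (vnorm(v) < 1e-12)
    stop("`v` must be non-zero", call. = FALSE)
  assert_unit(v)
  core$vectors %*% t(rotation_from_z(v))
}

#' Hemispherical boundary sampling at a node
#'
#' Rotates the sampling core to the node direction `v` and casts every core
#' ray from `C` with length cap `sampling_distance * r`. A ray that reaches
#' the cap without boundary termination records state 1 (its endpoint is
#' still inside the structure); a boundary-terminated ray records 0. The
#' states are arranged on the core's square grid, where connected nonzero
#' regions indicate branch continuations.
#'
#' @param vol a `ray_volume`.
#' @param C node location (continuous coordinates).
#' @param v unit node direction.
#' @param r local radius in voxels (`> 0`).
#' @param core a [hemisphere_core()].
#' @param detector a [boundary_detector()].
#' @param sampling_distance ray length cap in multiples of `r` (default 3;
#'   values outside `[1.5, 5]` are rejected, values outside the recommended
#'   `[2, 4]` band draw a warning).
#' @param step ray step length in voxels (default 1).
#' @return A `hemisphere_sample`: list with `valid`, per-vector `state`,
#'   the `grid` matrix, `origin`, `v`, `r`, rotation `frame`, and the
#'   resolved thresholds.
#' @export
hemisphere_sample <- function(vol, C, v, r, core = hemisphere_core(),
                              detector = boundary_detector(),
                              sampling_distance = 3, step = 1) {
  stopifnot(inherits(vol, "ray_volume"), r > 0, step > 0)
  assert_unit(v)
  if (sampling_distance < 1.5 || sampling_distance > 5)
    stop("`sampling_distance` must lie in [1.5, 5]", call. = FALSE)
  th <- resolve_detector(detector, vol, C, r)
  frame <- rotation_from_z(v)
  out <- list(valid = th$valid, origin = C, v = v, r = r, frame = frame,
              sampling_distance = sampling_distance, thresholds = th,
              state = NULL, grid = NULL)
  class(out) <- "hemisphere_sample"
  if (!th$valid) return(out)
  dirs <- core$vectors %*% t(frame)
  res <- cast_rays(vol, C, dirs, step, sampling_distance * r,
                   th$high, th$low)
  state <- as.integer(!res$boundary)
  grid <- matrix(0L, core$grid_size, core$grid_size)
  grid[cbind(core$gx, core$gy)] <- state
  out$state <- state
  out$grid <- grid
  out
}

#' @export
print.hemisphere_sample <- function(x, ...) {
  if (!x$valid) cat("<hemisphere_sample> invalid (origin in background)\n")
  else cat("<hemisphere_sample>", sum(x$state), "of", length(x$state),
           "rays inside at", x$sampling_distance, "x r\n")
  invisible(x)
}

#' Detect branch directions from a hemisphere sample
#'
#' Labels the connected components (8-connectivity) of nonzero cells on the
#' sample's square grid. Within each component, the cell maximizing the
#' Euclidean distance transform to the component's complement is selected
#' as the component's local center (ties broken by smallest inclination
#' ring, then smallest azimuth slot), mapped back to its hemisphere vector,
#' and rotated into the world frame. Each returned direction represents one
#' neurite branch; an all-zero or invalid sample yields no directions (a
#' terminal branch).
#'
#' @param sample a [hemisphere_sample()].
#' @param core the [hemisphere_core()] used to draw the sample.
#' @return matrix with one unit row per detected branch direction
#'   (0 rows when none).
#' @export
detect_branch_directions <- function(sample, core) {
  stopifnot(inherits(sample, "hemisphere_sample"),
            inherits(core, "hemisphere_core"))
  empty <- matrix(numeric(0), 0, 3)
  if (!sample$valid || is.null(sample$grid) || !any(sample$grid > 0))
    return(empty)
  lab <- label_components(sample$grid)
  idx_of <- matrix(NA_integer_, core$grid_size, core$grid_size)
  idx_of[cbind(core$gx, core$gy)] <- seq_along(core$ring)
  centers <- integer(0)
  for (comp in seq_len(max(lab))) {
    cells <- which(lab == comp, arr.ind = TRUE)
    d <- component_distance(cells, dim(lab))
    vi <- idx_of[cells]
    best <- order(-d, core$ring[vi], core$slot[vi])[1]
    centers <- c(centers, vi[best])
  }
  dirs <- core$vectors[centers, , drop = FALSE] %*% t(sample$frame)
  dirs / sqrt(rowSums(dirs^2))
}

# 8-connected component labeling of a small binary matrix (BFS flood fill).
label_components <- function(grid) {
  lab <- matrix(0L, nrow(grid), ncol(grid))
  nxt <- 0L
  nbr <- as.matrix(expand.grid(dx = -1:1, dy = -1:1))
  nbr <- nbr[!(nbr[, 1] == 0 & nbr[, 2] == 0), ]
  for (start in which(grid > 0 & lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      i <- (cur - 1L) %% nrow(grid) + 1L
      j <- (cur - 1L) %/% nrow(grid) + 1L
      ni <- i + nbr[, 1]; nj <- j + nbr[, 2]
      ok <- ni >= 1 & ni <= nrow(grid) & nj >= 1 & nj <= ncol(grid)
      lin <- (nj[ok] - 1L) * nrow(grid) + ni[ok]
      lin <- lin[grid[lin] > 0 & lab[lin] == 0L]
      lab[lin] <- nxt
      queue <- c(queue, lin)
    }
  }
  lab
}

# Euclidean distance from each component cell to the nearest cell of the
# component's complement (cells just outside the grid border count as
# complement). Brute force; grids here are at most (2M-1)^2 cells.
component_distance <- function(cells, grid_dim) {
  all_cells <- as.matrix(expand.grid(i = 0:(grid_dim[1] + 1L),
                                     j = 0:(grid_dim[2] + 1L)))
  in_comp <- paste(all_cells[, 1], all_cells[, 2]) %in%
    paste(cells[, 1], cells[, 2])
  comp_cells <- all_cells[!in_comp, , drop = FALSE]
  apply(cells, 1, function(c0)
    sqrt(min((comp_cells[, 1] - c0[1])^2 + (comp_cells[, 2] - c0[2])^2)))
}

#' Planar ring core for 2D rayburst refinement
#'
#' `N` unit 2-vectors at angles `2*pi*j/N`, `j = 0 .. N-1`, used as the
#' in-plane sampling core for centroid refinement and radius estimation.
#'
#' @param N ray count (`>= 8`; default 32).
#' @return A `ring_core`: list with `vectors` (N-by-2) and `N`.
#' @export
ring_core <- function(N = 32) {
  if (!is.numeric(N) || N < 8)
    stop("`N` must be an integer >= 8 for sufficient angular resolution",
         call. = FALSE)
  N <- as.integer(N)
  ang <- 2 * pi * (0:(N - 1L)) / N
  structure(list(vectors = cbind(cos(ang), sin(ang)), N = N),
            class = "ring_core")
}
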