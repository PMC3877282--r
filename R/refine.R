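#' Refinement configuration
#'
#' Parameters controlling iterative 2D rayburst refinement of node position
#' and radius.
#'
#' @param n_rays number of in-plane sampling rays (default 32).
#' @param centroid_exit_coeff radius-relative convergence threshold for the
#'   centroid iteration: iteration stops when successive centroids move
#'   less than this fraction of the current radius (default 0.05).
#' @param plane_exit_angle convergence threshold, in radians, on the angle
#'   between successive centerline directions (default `pi/36`).
#' @param max_centroid_iters,max_plane_iters iteration caps guarding
#'   non-convergent geometry (defaults 20 and 10); hitting a cap flags the
#'   result as not converged rather than failing.
#' @param step ray step length in voxels (default 1).
#' @return A `refine_config` list.
#' @export
refine_config <- function(n_rays = 32, centroid_exit_coeff = 0.05,
                          plane_exit_angle = pi / 36,
                          max_centroid_iters = 20, max_plane_iters = 10,
                          step = 1) {
  stopifnot(n_rays >= 8, centroid_exit_coeff > 0, centroid_exit_coeff < 1,
            plane_exit_angle > 0, max_centroid_iters >= 1,
            max_plane_iters >= 1, step > 0)
  structure(list(n_rays = as.integer(n_rays),
                 centroid_exit_coeff = centroid_exit_coeff,
                 plane_exit_angle = plane_exit_angle,
                 max_centroid_iters = as.integer(max_centroid_iters),
                 max_plane_iters = as.integer(max_plane_iters),
                 step = step),
            class = "refine_config")
}

#' Centroid refinement in a fixed cross-sectional plane
#'
#' Iterative 2D rayburst sampling in the plane through `C0` normal to `v`:
#' at each iteration all ring rays are cast from the current origin, the
#' boundary intersections are collected, and their mean becomes the next
#' origin. Iteration stops when successive origins move less than
#' `centroid_exit_coeff` times the current radius estimate, or at the
#' iteration cap. The radius is the mean ray length of a final sampling at
#' the converged origin. Ray length is capped at `4 * r0` to keep rays
#' bounded in confluent regions.
#'
#' If fewer than half the rays terminate at a boundary in some iteration
#' (open structure or image edge), the result is flagged not converged.
#'
#' @param vol a `ray_volume`.
#' @param C0 starting location.
#' @param v unit plane normal (the local centerline direction).
#' @param r0 radius guess in voxels (`> 0`).
#' @param ring a [ring_core()].
#' @param detector a [boundary_detector()].
#' @param cfg a [refine_config()].
#' @return list with `C`, `r`, `iters` and `converged`.
#' @export
refine_centroid_in_plane <- function(vol, C0, v, r0, ring = ring_core(),
                                     detector = boundary_detector(),
                                     cfg = refine_config()) {
  stopifnot(inherits(vol, "ray_volume"), r0 > 0,
            inherits(ring, "ring_core"))
  assert_unit(v)
  basis <- plane_basis(v)
  dirs <- ring$vectors[, 1] %o% basis$e1 + ring$vectors[, 2] %o% basis$e2
  max_len <- 4 * r0
  th <- resolve_detector(detector, vol, C0, r0)
  if (!th$valid)
    return(list(C = C0, r = r0, iters = 0L, converged = FALSE))
  C_cur <- as.double(C0)
  r_cur <- r0
  converged <- FALSE
  iters <- 0L
  for (i in seq_len(cfg$max_centroid_iters)) {
    iters <- i
    res <- cast_rays(vol, C_cur, dirs, cfg$step, max_len, th$high, th$low)
    hit <- res$boundary
    if (sum(hit) < ring$N / 2)
      return(list(C = C_cur, r = r_cur, iters = iters, converged = FALSE))
    C_next <- C_cur + colMeans(dirs[hit, , drop = FALSE] * res$length[hit])
    r_cur <- mean(res$length[hit])
    if (vnorm(C_next - C_cur) < cfg$centroid_exit_coeff * r_cur) {
      C_cur <- C_next
      converged <- TRUE
      break
    }
    C_cur <- C_next
  }
  # fresh sampling at the converged origin for the final radius
  res <- cast_rays(vol, C_cur, dirs, cfg$step, max_len, th$high, th$low)
  hit <- res$boundary
  if (sum(hit) < ring$N / 2)
    return(list(C = C_cur, r = r_cur, iters = iters, converged = FALSE))
  list(C = C_cur, r = mean(res$length[hit]), iters = iters,
       converged = converged)
}

#' Refine a node's location, direction and radius
#'
#' Repeats [refine_centroid_in_plane()] in successively re-oriented planes:
#' after each pass the centerline direction is recomputed as the unit
#' vector from the parent location to the refined position (the
#' parent-to-node segment represents the local centerline), and the next
#' pass samples the plane orthogonal to the updated direction. Iteration
#' stops when successive directions differ by less than `plane_exit_angle`,
#' or at the plane-iteration cap.
#'
#' @param vol a `ray_volume`.
#' @param C0 predicted node location.
#' @param v0 predicted unit direction.
#' @param r0 radius guess in voxels (typically the parent radius).
#' @param prev_C parent node location (must differ from `C0`).
#' @param ring a [ring_core()].
#' @param detector a [boundary_detector()].
#' @param cfg a [refine_config()].
#' @return A `refine_result` list: `C`, unit `v`, `r`, `centroid_iters`,
#'   `plane_iters`, `converged`.
#' @export
refine_node <- function(vol, C0, v0, r0, prev_C, ring = ring_core(),
                        detector = boundary_detector(),
                        cfg = refine_config()) {
  stopifnot(r0 > 0)
  assert_unit(v0)
  if (isTRUE(all.equal(as.double(prev_C), as.double(C0))))
    stop("`prev_C` must differ from `C0`", call. = FALSE)
  v <- as.double(v0)
  C_cur <- as.double(C0)
  r_cur <- r0
  centroid_iters <- 0L
  plane_iters <- 0L
  converged <- FALSE
  for (p in seq_len(cfg$max_plane_iters)) {
    plane_iters <- p
    inner <- refine_centroid_in_plane(vol, C_cur, v, r_cur, ring, detector,
                                      cfg)
    centroid_iters <- centroid_iters + inner$iters
    C_cur <- inner$C
    r_cur <- inner$r
    if (!inner$converged) {
      converged <- FALSE
      break
    }
    d <- C_cur - as.double(prev_C)
    if (vnorm(d) < 1e-9) {
      converged <- FALSE
      break
    }
    v_new <- unit(d)
    ang <- angle_between(v_new, v)
    v <- v_new
    if (ang < cfg$plane_exit_angle) {
      converged <- TRUE
      break
    }
  }
  structure(list(C = C_cur, v = v, r = r_cur,
                 centroid_iters = centroid_iters,
                 plane_iters = plane_iters, converged = converged),
            class = "refine_result")
}
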