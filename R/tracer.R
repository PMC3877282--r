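#' Tracer configuration
#'
#' All sampling parameters of the marching tracer, with the standard
#' defaults. Lengths are in voxels unless stated otherwise.
#'
#' @param sampling_distance 3D hemisphere ray cap, in multiples of the
#'   local radius (default 3.0; recommended range 2.0-4.0 — too small
#'   loses branches, too large creates redundancy).
#' @param location_distance parent-to-child spacing, in multiples of the
#'   parent radius (default 2.0, i.e. about one parent diameter;
#'   recommended range 1.5-2.5, and never more than `sampling_distance` —
#'   larger values are capped with a warning).
#' @param step ray step length in voxels (default 1.0).
#' @param M inclination division count of the hemisphere core (default 7).
#' @param epsilon_aniso anisotropy coefficient (default 1.0; about 1.0-1.1).
#' @param n_rays_2d number of 2D refinement rays (default 32).
#' @param centroid_exit_coeff centroid iteration exit distance, in
#'   multiples of the radius (default 0.05).
#' @param plane_exit_angle centerline iteration exit angle in radians
#'   (default `pi/36`).
#' @param min_radius minimum acceptable node radius in voxels (default
#'   0.5); branches thinner than this terminate.
#' @param max_nodes safety cap on emitted nodes (default 10000).
#' @param max_centroid_iters,max_plane_iters refinement iteration caps.
#' @return A `tracer_config` list.
#' @export
tracer_config <- function(sampling_distance = 3, location_distance = 2,
                          step = 1, M = 7, epsilon_aniso = 1,
                          n_rays_2d = 32, centroid_exit_coeff = 0.05,
                          plane_exit_angle = pi / 36, min_radius = 0.5,
                          max_nodes = 10000L, max_centroid_iters = 20,
                          max_plane_iters = 10) {
  stopifnot(sampling_distance >= 1.5, sampling_distance <= 5,
            location_distance > 0, step > 0, M >= 2, epsilon_aniso >= 1,
            min_radius > 0, max_nodes >= 1)
  if (sampling_distance < 2 || sampling_distance > 4)
    warning("`sampling_distance` outside the recommended [2, 4] band")
  if (location_distance > sampling_distance) {
    warning("`location_distance` capped at `sampling_distance`")
    location_distance <- sampling_distance
  }
  structure(list(sampling_distance = sampling_distance,
                 location_distance = location_distance, step = step,
                 M = as.integer(M), epsilon_aniso = epsilon_aniso,
                 n_rays_2d = as.integer(n_rays_2d),
                 centroid_exit_coeff = centroid_exit_coeff,
                 plane_exit_angle = plane_exit_angle,
                 min_radius = min_radius, max_nodes = as.integer(max_nodes),
                 max_centroid_iters = as.integer(max_centroid_iters),
                 max_plane_iters = as.integer(max_plane_iters)),
            class = "tracer_config")
}

as_refine_config <- function(cfg) {
  refine_config(n_rays = cfg$n_rays_2d,
                centroid_exit_coeff = cfg$centroid_exit_coeff,
                plane_exit_angle = cfg$plane_exit_angle,
                max_centroid_iters = cfg$max_centroid_iters,
                max_plane_iters = cfg$max_plane_iters,
                step = cfg$step)
}

#' Predict a child node from a parent and a branch direction
#'
#' The child is placed `location_distance * parent_r` along the branch
#' direction (about one parent diameter away), pointing along the branch,
#' with the parent's radius as initial guess.
#'
#' @param parent list or row with fields `C` (location) and `r` (radius).
#' @param branch_dir unit 3-vector.
#' @param cfg a [tracer_config()].
#' @return list with `C_pred`, `v_pred`, `r_pred`.
#' @export
predict_child <- function(parent, branch_dir, cfg = tracer_config()) {
  stopifnot(parent$r > 0)
  assert_unit(branch_dir)
  list(C_pred = parent$C + cfg$location_distance * parent$r * branch_dir,
       v_pred = as.double(branch_dir),
       r_pred = parent$r)
}

#' Seed a trace at a chosen foreground point
#'
#' Estimates an initial radius by a full-sphere rayburst (the minimum
#' boundary-terminated ray length, matching the node definition of radius
#' as the minimum distance to the structure boundary), picks an initial
#' direction from the dominant branch cluster, refines the seed node, and
#' performs two hemisphere samplings in opposite directions (`v` and `-v`)
#' so branches on both sides of the seed are detected.
#'
#' @param vol a `ray_volume`.
#' @param seed_point location inside the structure.
#' @param cfg a [tracer_config()].
#' @param detector a [boundary_detector()].
#' @return list with `node` (fields `C`, `v`, `r`) and `children`, a list
#'   of [predict_child()] predictions.
#' @export
seed_node <- function(vol, seed_point, cfg = tracer_config(),
                      detector = boundary_detector()) {
  stopifnot(inherits(vol, "ray_volume"))
  seed_point <- as.double(seed_point)
  core <- hemisphere_core(cfg$M, cfg$epsilon_aniso)
  ring <- ring_core(cfg$n_rays_2d)
  rcfg <- as_refine_config(cfg)
  th <- resolve_detector(detector, vol, seed_point, radius = 3)
  if (!th$valid)
    stop("seed point is in background; pick a point inside the structure",
         call. = FALSE)
  # full-sphere burst for the initial radius
  dirs <- rbind(core$vectors, -core$vectors)
  burst <- cast_rays(vol, seed_point, dirs, cfg$step,
                     max_length = max(vol$shape), th$high, th$low)
  hit <- burst$boundary & burst$length > 0
  r0 <- if (any(hit)) max(min(burst$length[hit]), cfg$min_radius)
        else cfg$min_radius
  # initial direction: center of the largest branch cluster over the two
  # opposite canonical hemispheres
  v0 <- dominant_direction(vol, seed_point, r0, core, detector, cfg)
  if (is.null(v0)) v0 <- c(0, 0, 1)
  refined <- refine_node(vol, seed_point, v0, r0,
                         prev_C = seed_point - r0 * v0, ring, detector,
                         rcfg)
  node <- list(C = refined$C, v = refined$v, r = max(refined$r, cfg$min_radius))
  children <- list()
  for (sgn in c(1, -1)) {
    hs <- hemisphere_sample(vol, node$C, sgn * node$v, node$r, core,
                            detector, cfg$sampling_distance, cfg$step)
    bd <- detect_branch_directions(hs, core)
    for (i in seq_len(nrow(bd)))
      children[[length(children) + 1L]] <-
        predict_child(node, bd[i, ], cfg)
  }
  list(node = node, children = children)
}

# Largest-cluster direction over the two opposite canonical hemispheres.
dominant_direction <- function(vol, C, r, core, detector, cfg) {
  best <- NULL
  best_size <- -1L
  for (v in list(c(0, 0, 1), c(0, 0, -1))) {
    hs <- hemisphere_sample(vol, C, v, r, core, detector,
                            cfg$sampling_distance, cfg$step)
    if (!hs$valid || !any(hs$grid > 0)) next
    lab <- label_components(hs$grid)
    sizes <- tabulate(lab[lab > 0])
    bd <- detect_branch_directions(hs, core)
    for (i in seq_len(nrow(bd))) {
      if (sizes[i] > best_size) {
        best_size <- sizes[i]
        best <- bd[i, ]
      }
    }
  }
  best
}

#' Trace a whole tree from seed points
#'
#' The marching reconstruction: every seed spawns an initial node and
#' child predictions ([seed_node()]); pending predictions are kept in a
#' FIFO queue and popped in order. Each popped prediction is refined
#' ([refine_node()]); refinement failure, a radius below `min_radius`, a
#' location outside the volume, or proximity to an already-emitted node on
#' a different path (the loop guard) terminates that branch. Otherwise the
#' node is emitted, a hemisphere sampling in its forward direction detects
#' branch continuations, and one child prediction per detected branch is
#' queued. Tracing stops when the queue empties or `max_nodes` is reached.
#'
#' The pipeline contains no randomness: identical volume, seeds and
#' configuration give identical trees.
#'
#' @param vol a `ray_volume`.
#' @param seeds numeric 3-vector, n-by-3 matrix, or list of locations.
#' @param cfg a [tracer_config()].
#' @param detector a [boundary_detector()].
#' @return A [neuron_tree()] tibble (SWC columns), with attributes
#'   `n_dropped` (predictions discarded) and `truncated` (hit `max_nodes`).
#' @export
trace_neuron <- function(vol, seeds, cfg = tracer_config(),
                         detector = boundary_detector()) {
  stopifnot(inherits(vol, "ray_volume"))
  if (is.list(seeds) && !is.data.frame(seeds))
    seeds <- do.call(rbind, seeds)
  if (!is.matrix(seeds)) seeds <- matrix(as.double(seeds), ncol = 3L)
  if (ncol(seeds) != 3L) stop("`seeds` must be x,y,z locations", call. = FALSE)
  core <- hemisphere_core(cfg$M, cfg$epsilon_aniso)
  ring <- ring_core(cfg$n_rays_2d)
  rcfg <- as_refine_config(cfg)

  # emitted-node store
  cap <- 256L
  P <- matrix(NA_real_, cap, 3)
  R <- numeric(cap)
  PAR <- integer(cap)
  TYPE <- integer(cap)
  n_nodes <- 0L
  emit <- function(C, r, parent, type = 3L) {
    n_nodes <<- n_nodes + 1L
    if (n_nodes > cap) {
      cap <<- cap * 2L
      P2 <- matrix(NA_real_, cap, 3); P2[seq_len(n_nodes - 1L), ] <- P
      P <<- P2
      length(R) <<- cap; length(PAR) <<- cap; length(TYPE) <<- cap
    }
    P[n_nodes, ] <<- C; R[n_nodes] <<- r
    PAR[n_nodes] <<- parent; TYPE[n_nodes] <<- type
    n_nodes
  }
  # proximity of a point to any emitted node except the listed ids
  near_existing <- function(C, exclude) {
    if (n_nodes == 0L) return(FALSE)
    idx <- setdiff(seq_len(n_nodes), exclude)
    if (length(idx) == 0L) return(FALSE)
    d2 <- (P[idx, 1] - C[1])^2 + (P[idx, 2] - C[2])^2 + (P[idx, 3] - C[3])^2
    any(d2 < R[idx]^2)
  }
  inside <- function(C) all(C >= 0) && all(C <= vol$shape - 1)

  queue <- vector("list", 64L)
  q_head <- 1L; q_tail <- 0L
  push <- function(item) {
    q_tail <<- q_tail + 1L
    if (q_tail > length(queue)) length(queue) <<- 2L * length(queue)
    queue[[q_tail]] <<- item
  }

  n_seeded <- 0L
  for (s in seq_len(nrow(seeds))) {
    sn <- tryCatch(seed_node(vol, seeds[s, ], cfg, detector),
                   error = function(e) NULL)
    if (is.null(sn)) next
    n_seeded <- n_seeded + 1L
    sid <- emit(sn$node$C, sn$node$r, -1L)
    for (ch in sn$children)
      push(list(C = ch$C_pred, v = ch$v_pred, r = ch$r_pred,
                parent = sid, grandparent = -1L))
  }
  if (n_seeded == 0L)
    stop("no valid seeds: every seed point is in background", call. = FALSE)

  n_dropped <- 0L
  truncated <- FALSE
  while (q_head <= q_tail) {
    if (n_nodes >= cfg$max_nodes) { truncated <- TRUE; break }
    item <- queue[[q_head]]; queue[q_head] <- list(NULL); q_head <- q_head + 1L
    if (!inside(item$C)) { n_dropped <- n_dropped + 1L; next }
    prev_C <- P[item$parent, ]
    refined <- tryCatch(
      refine_node(vol, item$C, item$v, item$r, prev_C, ring, detector, rcfg),
      error = function(e) NULL)
    if (is.null(refined) || !refined$converged ||
        refined$r < cfg$min_radius || !inside(refined$C)) {
      n_dropped <- n_dropped + 1L; next
    }
    # loop guard: proximity to an already-emitted node terminates the
    # branch, except the immediate family (parent, grandparent, siblings)
    # whose closeness is expected right after a branch point
    siblings <- which(PAR[seq_len(n_nodes)] == item$parent)
    excl <- c(item$parent, item$grandparent, siblings)
    if (near_existing(refined$C, excl)) { n_dropped <- n_dropped + 1L; next }
    nid <- emit(refined$C, refined$r, item$parent)
    hs <- hemisphere_sample(vol, refined$C, refined$v, refined$r, core,
                            detector, cfg$sampling_distance, cfg$step)
    bd <- detect_branch_directions(hs, core)
    for (i in seq_len(nrow(bd))) {
      pred <- predict_child(list(C = refined$C, r = refined$r), bd[i, ], cfg)
      if (near_existing(pred$C_pred, c(nid, item$parent, siblings))) {
        n_dropped <- n_dropped + 1L
        next
      }
      push(list(C = pred$C_pred, v = pred$v_pred, r = pred$r_pred,
                parent = nid, grandparent = item$parent))
    }
  }
  if (truncated)
    warning("max_nodes reached; reconstruction truncated")

  idx <- seq_len(n_nodes)
  tree <- neuron_tree(tibble::tibble(
    id = idx, type = TYPE[idx], x = P[idx, 1], y = P[idx, 2],
    z = P[idx, 3], radius = R[idx], parent = PAR[idx]))
  attr(tree, "n_dropped") <- n_dropped
  attr(tree, "truncated") <- truncated
  attr(tree, "config") <- cfg
  tree
}
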