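#' Boundary detectors for ray termination
#'
#' Rays walking through the volume are terminated by a two-level hysteresis
#' classifier: a sample is foreground when its intensity is at least
#' `high`, background when it is below `low`, and inherits the previous
#' sample's class in between. The hysteresis band suppresses single-voxel
#' flicker along a ray.
#'
#' In `"fixed"` mode the two thresholds are used as given. In `"adaptive"`
#' mode (the default) they are recomputed at every ray-cast batch origin
#' from local statistics: the local foreground level `F` is the intensity
#' at the origin, the local background level `B` is the
#' `background_quantile` quantile of intensities in a cubic neighborhood of
#' half-width `neighborhood_scale` times the current radius, and
#' `high = B + high_coeff * (F - B)`, `low = B + low_coeff * (F - B)`.
#' An origin whose local contrast `F - B` falls below `min_contrast` is
#' classified background (invalid), so rays started in pure background
#' terminate immediately.
#'
#' @param mode `"adaptive"` or `"fixed"`.
#' @param high,low fixed-mode thresholds, normalized intensities in
#'   `[0, 1]` with `low <= high`.
#' @param high_coeff,low_coeff adaptive-mode interpolation coefficients
#'   between local background and foreground (defaults 0.5 and 0.25).
#' @param background_quantile quantile of the local neighborhood used as
#'   the background estimate (default 0.1).
#' @param neighborhood_scale neighborhood half-width in multiples of the
#'   current radius (default 3).
#' @param min_contrast minimum normalized local contrast for a valid
#'   origin (default 0.05, adaptive mode only).
#' @return A `boundary_detector` object.
#' @export
boundary_detector <- function(mode = c("adaptive", "fixed"),
                              high = 0.5, low = 0.25,
                              high_coeff = 0.5, low_coeff = 0.25,
                              background_quantile = 0.1,
                              neighborhood_scale = 3,
                              min_contrast = 0.05) {
  mode <- match.arg(mode)
  stopifnot(low <= high, low_coeff <= high_coeff,
            background_quantile >= 0, background_quantile <= 1,
            neighborhood_scale > 0, min_contrast >= 0)
  structure(list(mode = mode, high = high, low = low,
                 high_coeff = high_coeff, low_coeff = low_coeff,
                 background_quantile = background_quantile,
                 neighborhood_scale = neighborhood_scale,
                 min_contrast = min_contrast),
            class = "boundary_detector")
}

#' @export
print.boundary_detector <- function(x, ...) {
  if (x$mode == "fixed")
    cat("<boundary_detector> fixed: high =", x$high, "low =", x$low, "\n")
  else
    cat("<boundary_detector> adaptive: high/low coeff =", x$high_coeff, "/",
        x$low_coeff, ", background quantile =", x$background_quantile, "\n")
  invisible(x)
}

# Resolve a detector to concrete (high, low) thresholds at a ray-cast batch
# origin. Returns high, low, foreground level F, background estimate B and
# whether the origin itself classifies as a valid foreground start.
resolve_detector <- function(detector, vol, origin, radius = 3) {
  stopifnot(inherits(detector, "boundary_detector"))
  f <- sample_intensity(vol, origin)
  if (detector$mode == "fixed") {
    return(list(high = detector$high, low = detector$low,
                foreground = f, background = NA_real_,
                valid = f >= detector$low))
  }
  h <- max(1, ceiling(detector$neighborhood_scale * radius))
  ctr <- round(origin)
  lo <- pmax(ctr - h, 0)
  hi <- pmin(ctr + h, vol$shape - 1)
  nb <- vol$data[(lo[1]:hi[1]) + 1, (lo[2]:hi[2]) + 1, (lo[3]:hi[3]) + 1]
  b <- as.numeric(quantile(nb, probs = detector$background_quantile,
                           names = FALSE))
  if (f < b) f <- b
  contrast <- f - b
  list(high = b + detector$high_coeff * contrast,
       low = b + detector$low_coeff * contrast,
       foreground = f, background = b,
       valid = contrast >= detector$min_contrast)
}

#' Cast a single ray until it exits the structure
#'
#' Walks `origin + k * step * direction` for `k = 1, 2, ...` and stops at
#' the first sample classified background by the detector's hysteresis
#' rule (returning length `(k - 1) * step` with `terminated_by_boundary =
#' TRUE`), or when the walk would exceed `max_length` (returning
#' `max_length` with `terminated_by_boundary = FALSE`). An origin that
#' itself classifies as background returns length 0 with the boundary flag
#' set.
#'
#' @param vol a `ray_volume`.
#' @param origin continuous 3D coordinate.
#' @param direction unit 3-vector (tolerance 1e-6).
#' @param step step length in voxels (default 1).
#' @param max_length ray length cap in voxels.
#' @param detector a [boundary_detector()].
#' @param radius local radius estimate used to size the adaptive detector's
#'   neighborhood (default 3 voxels).
#' @return list with `length` (voxels) and `terminated_by_boundary`.
#' @export
cast_ray <- function(vol, origin, direction, step = 1, max_length,
                     detector = boundary_detector(), radius = 3) {
  stopifnot(inherits(vol, "ray_volume"), step > 0, max_length > 0)
  if (any(!is.finite(origin)) || length(origin) != 3L)
    stop("`origin` must be a finite 3-vector", call. = FALSE)
  assert_unit(direction)
  th <- resolve_detector(detector, vol, origin, radius)
  if (!th$valid)
    return(list(length = 0, terminated_by_boundary = TRUE))
  res <- cast_rays_cpp(vol$data, as.integer(vol$shape), as.double(origin),
                       matrix(direction, 1, 3), step, max_length,
                       th$high, th$low)
  list(length = res$length[1], terminated_by_boundary = res$boundary[1])
}

# Batch ray cast with pre-resolved thresholds (internal hot path).
cast_rays <- function(vol, origin, dirs, step, max_length, high, low) {
  cast_rays_cpp(vol$data, as.integer(vol$shape), as.double(origin),
                dirs, step, as.double(max_length), high, low)
}
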