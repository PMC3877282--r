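# Shared analytic fixtures, all generated in code at test time.

# binary detector matched to normalized binary phantoms
fixed_detector <- function() boundary_detector("fixed", high = 0.5, low = 0.25)

# straight cylinder along z, centered in x/y
cylinder_phantom <- function(radius = 4, shape = c(41, 41, 81),
                             z0 = 8, z1 = shape[3] - 9) {
  c0 <- (shape[1] - 1) / 2
  phantom_tube(shape = shape, start = c(c0, c0, z0), end = c(c0, c0, z1),
               radius = radius)
}

# symmetric Y junction: trunk along +z up to z_junction, two daughters at
# +-35 degrees in the xz plane
y_phantom <- function(radius = 3, shape = c(81, 81, 81), z_junction = 40,
                      limb = 30) {
  a <- 35 * pi / 180
  d1 <- c(sin(a), 0, cos(a))
  d2 <- c(-sin(a), 0, cos(a))
  c0 <- (shape[1] - 1) / 2
  j <- c(c0, c0, z_junction)
  arr <- array(0, dim = shape)
  ras <- getFromNamespace("rasterize_capsule", "rayburst")
  arr <- ras(arr, c(c0, c0, 10), j, radius, radius)
  arr <- ras(arr, j, j + limb * d1, radius, radius)
  arr <- ras(arr, j, j + limb * d2, radius, radius)
  list(volume = as_volume(arr), junction = j, radius = radius,
       daughters = rbind(d1, d2))
}

# solid ball of the given radius, centered
ball_phantom <- function(radius = 8, shape = c(41, 41, 41)) {
  c0 <- (shape - 1) / 2
  idx <- expand.grid(x = 0:(shape[1] - 1), y = 0:(shape[2] - 1),
                     z = 0:(shape[3] - 1))
  inside <- (idx$x - c0[1])^2 + (idx$y - c0[2])^2 + (idx$z - c0[3])^2 <=
    radius^2
  list(volume = as_volume(array(as.double(inside) * 255, dim = shape)),
       center = c0)
}

# simple hand-built chain tree
chain_tree <- function(n = 3, spacing = 5, radius = 1) {
  neuron_tree(tibble::tibble(
    id = seq_len(n), type = 3L, x = (seq_len(n) - 1) * spacing, y = 0,
    z = 0, radius = radius,
    parent = c(-1L, seq_len(n - 1))))
}

angle_between_test <- function(a, b) {
  acos(max(-1, min(1, sum(a * b) / sqrt(sum(a^2) * sum(b^2)))))
}

unit_test <- function(x) x / sqrt(sum(x^2))
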