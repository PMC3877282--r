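#' Image volumes
#'
#' A `ray_volume` holds a 3D scalar intensity grid with per-axis voxel
#' spacing. Intensities are normalized to `[0, 1]` by min-max over the grid
#' (a constant grid maps to 0). Coordinates throughout the package are
#' continuous, 0-based and voxel-centered: the center of voxel
#' `data[i+1, j+1, k+1]` is at `(i, j, k)`, with axis order `(x, y, z)` and
#' `z` the slice axis. Queries outside the grid return the background
#' value 0.
#'
#' @param data numeric 3D array of intensities, indexed `[x, y, z]`.
#' @param spacing positive length-3 numeric, physical voxel size per axis
#'   (relative units). Stored as metadata; ray lengths are expressed in
#'   voxels and axial anisotropy is handled by the sampling-core anisotropy
#'   coefficient (see [hemisphere_core()]).
#' @param normalize normalize intensities to `[0, 1]` by min-max (default).
#' @return A `ray_volume` object.
#' @seealso [load_volume()], [sample_intensity()], [cast_ray()]
#' @export
as_volume <- function(data, spacing = c(1, 1, 1), normalize = TRUE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers", call. = FALSE)
  data <- array(as.double(data), dim = dim(data))
  if (normalize) {
    rng <- range(data, finite = TRUE)
    data <- if (rng[2] > rng[1]) (data - rng[1]) / (rng[2] - rng[1])
            else array(0, dim = dim(data))
  }
  structure(list(data = data, spacing = spacing, shape = dim(data)),
            class = "ray_volume")
}

#' @export
print.ray_volume <- function(x, ...) {
  cat("<ray_volume> ", paste(x$shape, collapse = " x "),
      " voxels, spacing (", paste(format(x$spacing), collapse = ", "),
      "), intensity range [", format(min(x$data)), ", ",
      format(max(x$data)), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.ray_volume <- function(x) x$shape

#' Load an image volume from disk
#'
#' Reads a multi-page TIFF, a directory of numbered single-page TIFFs
#' (grayscale, 8/16-bit), or a raw binary grid accompanied by a small text
#' sidecar (`<path>.meta` with lines `dims: nx ny nz`, `dtype: uint8|uint16|
#' float32`, and optionally `spacing: sx sy sz`). Intensities are min-max
#' normalized to `[0, 1]`.
#'
#' @param path file or directory path.
#' @param spacing optional per-axis voxel size; overrides any sidecar value.
#'   Defaults to `(1, 1, 1)`.
#' @param axial_supersample integer factor `>= 1`; when `> 1` the volume is
#'   linearly interpolated along `z` to `(nz - 1) * factor + 1` slices. This
#'   is the optional axial super-sampling for strongly anisotropic stacks;
#'   the alternative is to leave the grid alone and raise the sampling-core
#'   anisotropy coefficient.
#' @return A [as_volume()] `ray_volume`.
#' @export
load_volume <- function(path, spacing = NULL, axial_supersample = 1L) {
  if (!file.exists(path))
    stop("cannot read volume: no such file or directory: ", path,
         call. = FALSE)
  side_spacing <- NULL
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L)
      stop("no TIFF slices found in directory: ", path, call. = FALSE)
    slices <- lapply(files, function(f) slice_matrix(tiff::readTIFF(f)))
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    slices <- lapply(pages, slice_matrix)
  } else {
    raw <- read_raw_grid(path)
    slices <- raw$slices
    side_spacing <- raw$spacing
  }
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent slice dimensions in ", path, call. = FALSE)
  arr <- array(unlist(slices, use.names = FALSE),
               dim = c(dims[1, 1], dims[2, 1], length(slices)))
  if (axial_supersample > 1L) arr <- supersample_z(arr, as.integer(axial_supersample))
  spacing <- spacing %||% side_spacing %||% c(1, 1, 1)
  as_volume(arr, spacing = spacing)
}

# readTIFF returns a matrix [row = y, col = x] scaled to [0, 1]; transpose
# to the package's [x, y] slice convention. Multi-channel pages are
# collapsed to their first channel.
slice_matrix <- function(m) {
  if (length(dim(m)) == 3L) m <- m[, , 1]
  t(m)
}

read_raw_grid <- function(path) {
  meta_path <- paste0(path, ".meta")
  if (!file.exists(meta_path))
    stop("raw volume requires a text sidecar: ", meta_path, call. = FALSE)
  meta <- readLines(meta_path, warn = FALSE)
  field <- function(key) {
    ln <- grep(paste0("^", key, ":"), meta, value = TRUE)
    if (length(ln) == 0L) return(NULL)
    strsplit(trimws(sub(paste0("^", key, ":"), "", ln[1])), "\\s+")[[1]]
  }
  dims <- as.integer(field("dims"))
  if (length(dims) != 3L || any(is.na(dims)))
    stop("sidecar `dims:` must give nx ny nz: ", meta_path, call. = FALSE)
  dtype <- (field("dtype") %||% "uint8")[1]
  spc <- field("spacing")
  spc <- if (is.null(spc)) NULL else as.numeric(spc)
  n <- prod(dims)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- switch(dtype,
    uint8   = as.double(readBin(con, "integer", n, size = 1, signed = FALSE)),
    uint16  = as.double(readBin(con, "integer", n, size = 2, signed = FALSE,
                                endian = "little")),
    float32 = readBin(con, "double", n, size = 4, endian = "little"),
    stop("unsupported raw dtype: ", dtype, call. = FALSE))
  if (length(vals) < n)
    stop("raw file shorter than dims imply: ", path, call. = FALSE)
  arr <- array(vals, dim = dims)
  list(slices = lapply(seq_len(dims[3]), function(k) arr[, , k]),
       spacing = spc)
}

supersample_z <- function(arr, f) {
  nz <- dim(arr)[3]
  if (nz < 2L) return(arr)
  new_z <- seq(0, nz - 1, by = 1 / f)
  out <- array(0, dim = c(dim(arr)[1:2], length(new_z)))
  for (i in seq_along(new_z)) {
    z <- new_z[i]
    z0 <- floor(z); fz <- z - z0
    lo <- arr[, , z0 + 1]
    hi <- arr[, , min(z0 + 2, nz)]
    out[, , i] <- lo * (1 - fz) + hi * fz
  }
  out
}

#' Write a volume as a multi-page 8-bit TIFF
#'
#' Intensities (already in `[0, 1]`) are quantized to 8 bits. Loading the
#' file back with [load_volume()] reproduces the grid exactly at 8-bit
#' resolution.
#'
#' @param vol a `ray_volume`.
#' @param path output file path (`.tif`).
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ray_volume"))
  slices <- lapply(seq_len(vol$shape[3]), function(k) t(vol$data[, , k]))
  tiff::writeTIFF(slices, path, bits.per.sample = 8L)
  invisible(path)
}

#' Sample intensity at continuous coordinates
#'
#' Trilinear interpolation of the 8 voxels surrounding each query point.
#' Points outside the grid return the background value 0.
#'
#' @param vol a `ray_volume`.
#' @param point numeric 3-vector or n-by-3 matrix of continuous, 0-based,
#'   voxel-centered coordinates.
#' @return numeric vector of interpolated intensities.
#' @export
sample_intensity <- function(vol, point) {
  stopifnot(inherits(vol, "ray_volume"))
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 3L)
  if (ncol(pts) != 3L || any(!is.finite(pts)))
    stop("`point` must be finite 3D coordinates", call. = FALSE)
  trilinear_cpp(vol$data, as.integer(vol$shape), pts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
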