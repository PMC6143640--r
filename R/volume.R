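#' Greyscale 3D volume with physical metadata
#'
#' The basic container of the package: a numeric 3D array on an isotropic
#' grid, together with the voxel size in micrometres and a labelling of the
#' three grid axes with the anatomical reference frame (`"x"` mediolateral,
#' `"y"` anteroposterior, `"z"` inferosuperior). Indices are 0-based in all
#' physical-coordinate conversions: the centre of voxel `(i, j, k)` sits at
#' `c(i, j, k) * voxel_size` micrometres.
#'
#' @param data numeric 3D array (grid order x, y, z).
#' @param voxel_size isotropic voxel edge length in micrometres (> 0).
#' @param axes character(3), a permutation of `c("x", "y", "z")` mapping grid
#'   axes to anatomical axes.
#' @return an object of class `volume3d`.
#' @export
volume3d <- function(data, voxel_size, axes = c("x", "y", "z")) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (micrometres)")
  if (!setequal(axes, c("x", "y", "z")))
    stop("`axes` must be a permutation of c('x', 'y', 'z')")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 axes = axes),
            class = "volume3d")
}

#' Binary 3D mask congruent with a volume
#'
#' A logical grid sharing shape and voxel size with the volume it was derived
#' from, carrying a provenance record of the operations applied so a
#' segmentation chain can be replayed.
#'
#' @param data logical 3D array.
#' @param voxel_size voxel edge length (micrometres).
#' @param axes axis labels, as in [volume3d()].
#' @param provenance character vector describing the operations applied.
#' @return an object of class `mask3d`.
#' @export
mask3d <- function(data, voxel_size, axes = c("x", "y", "z"),
                   provenance = character()) {
  if (!is.array(data) || length(dim(data)) != 3L || !is.logical(data))
    stop("`data` must be a logical 3D array")
  v <- volume3d(array(0, dim(data)), voxel_size, axes)
  structure(list(data = data, voxel_size = v$voxel_size, axes = v$axes,
                 provenance = provenance),
            class = "mask3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels, %.4g um/voxel, axes (%s)\n",
              d[1], d[2], d[3], x$voxel_size, paste(x$axes, collapse = ", ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.mask3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mask3d> %d x %d x %d voxels, %.4g um/voxel, %d foreground\n",
              d[1], d[2], d[3], x$voxel_size, sum(x$data)))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)
#' @export
dim.mask3d <- function(x) dim(x$data)

grid_extent <- function(x) dim(x$data) * x$voxel_size

check_congruent <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("grids are not congruent (shape mismatch)")
  if (abs(a$voxel_size - b$voxel_size) > 1e-9)
    stop("grids are not congruent (voxel size mismatch)")
  invisible(TRUE)
}

#' Crop a region of interest
#'
#' Bounds follow the package-wide index convention: 0-based, half-open
#' `[lo, hi)` ranges per axis. Metadata (voxel size, axis labels) is
#' preserved and the origin offset is recorded (on masks, in the
#' provenance; on volumes, as attribute `origin_offset`, in voxels).
#'
#' @param x a `volume3d` or `mask3d`.
#' @param bounds list with elements `x`, `y`, `z`, each `c(lo, hi)` 0-based
#'   half-open; missing elements default to the full range.
#' @return object of the same class as `x`.
#' @export
crop_roi <- function(x, bounds) {
  d <- dim(x$data)
  ax <- c("x", "y", "z")
  lo <- integer(3); hi <- integer(3)
  for (a in seq_len(3)) {
    b <- bounds[[ax[a]]]
    if (is.null(b)) b <- c(0L, d[a])
    if (length(b) != 2L || b[1] < 0 || b[2] > d[a] || b[1] >= b[2])
      stop(sprintf("invalid bounds for axis %s: [%s, %s) with extent %d",
                   ax[a], b[1], b[2], d[a]))
    lo[a] <- b[1]; hi[a] <- b[2]
  }
  sub <- x$data[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3],
                drop = FALSE]
  out <- x
  out$data <- sub
  prev <- attr(x$data, "origin_offset")
  off <- if (is.null(prev)) lo else prev + lo
  attr(out$data, "origin_offset") <- off
  if (inherits(x, "mask3d"))
    out$provenance <- c(x$provenance,
                        sprintf("crop_roi(%s)", paste(lo, collapse = ",")))
  out
}

# Shift an array along one axis by `by` voxels with mirror padding
# (reflection about the boundary voxel, "symmetric" style: the edge voxel
# is not repeated beyond itself; index i maps to 2 - i below the range).
shift_mirror <- function(arr, axis, by) {
  n <- dim(arr)[axis]
  idx <- seq_len(n) + by
  idx <- ifelse(idx < 1L, 2L - idx, idx)
  idx <- ifelse(idx > n, 2L * n - idx, idx)
  idx <- pmax(1L, pmin(n, idx))
  switch(axis,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

# Separable convolution with a 1D kernel along one axis, mirror padding.
convolve_axis <- function(arr, kernel, axis) {
  r <- (length(kernel) - 1L) / 2L
  out <- array(0, dim(arr))
  for (o in seq_along(kernel))
    out <- out + kernel[o] * shift_mirror(arr, axis, o - 1L - r)
  out
}

# Truncated, renormalised Gaussian kernel of half-width `radius`.
gauss_kernel <- function(sigma, radius) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# 3D separable Gaussian smoothing with mirror padding.
smooth_gauss <- function(arr, sigma, radius = ceiling(3 * sigma)) {
  if (sigma <= 0) return(arr)
  k <- gauss_kernel(sigma, radius)
  for (axis in 1:3) arr <- convolve_axis(arr, k, axis)
  arr
}

# Physical coordinates (um) of voxel centres for a flat index vector.
index_to_um <- function(idx, dim3, voxel_size) {
  idx0 <- idx - 1L
  i <- idx0 %% dim3[1]
  j <- (idx0 %/% dim3[1]) %% dim3[2]
  k <- idx0 %/% (dim3[1] * dim3[2])
  cbind(i, j, k) * voxel_size
}

# Evaluate a seeded expression without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
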