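#' Threshold a greyscale volume
#'
#' Coarse segmentation of the fibrous phase: foreground is every voxel whose
#' intensity lies strictly above the threshold. The threshold is either
#' Otsu's value (maximising between-class variance on a 256-bin histogram)
#' or a fixed intensity. The chosen value is logged in the mask provenance.
#'
#' @param volume a `volume3d`.
#' @param method `"otsu"` or `"fixed"`.
#' @param value threshold intensity when `method = "fixed"`.
#' @return a `mask3d`.
#' @export
threshold_volume <- function(volume, method = c("otsu", "fixed"),
                             value = NULL) {
  method <- match.arg(method)
  v <- volume$data
  if (method == "otsu") {
    if (max(v) == min(v))
      stop("otsu thresholding requires a non-constant volume")
    thr <- otsu_threshold(as.vector(v))
  } else {
    if (is.null(value)) stop("method 'fixed' requires `value`")
    thr <- value
  }
  mask3d(v > thr, volume$voxel_size, volume$axes,
         provenance = sprintf("threshold(%s=%.6g)", method, thr))
}

# Otsu's threshold on a 256-bin histogram; returns the intensity (bin edge)
# maximising between-class variance.
otsu_threshold <- function(v, n_bins = 256L) {
  lo <- min(v); hi <- max(v)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  h <- tabulate(pmin(n_bins, findInterval(v, edges, rightmost.closed = TRUE)),
                nbins = n_bins)
  p <- h / sum(h)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w0 <- cumsum(p)
  m0 <- cumsum(p * centers)
  mt <- m0[n_bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sb2 <- rep(-Inf, n_bins)
  sb2[valid] <- (mt * w0[valid] - m0[valid])^2 / (w0[valid] * w1[valid])
  edges[which.max(sb2) + 1L]
}

# ---- binary morphology with a discrete ball structuring element ------------
# Ball of radius r = all integer offsets with squared norm <= r^2. Voxels
# outside the grid are treated as background (erosion shrinks at borders,
# dilation cannot create voxels outside the grid).

ball_offsets <- function(r) {
  s <- (-floor(r)):floor(r)
  g <- expand.grid(dx = s, dy = s, dz = s)
  g[g$dx^2 + g$dy^2 + g$dz^2 <= r^2, , drop = FALSE]
}

morph_dilate <- function(arr, r) {
  d2 <- edt_sq_cpp(!arr, dim(arr))       # distance to nearest foreground
  array(d2 <= r^2, dim(arr))
}

morph_erode <- function(arr, r) {
  d <- dim(arr)
  pad <- as.integer(ceiling(r))
  big <- array(FALSE, d + 2L * pad)
  big[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- arr
  d2 <- array(edt_sq_cpp(big, dim(big)), dim(big))  # distance to background
  out <- d2[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])]
  array(out > r^2, d)
}

shift_zero <- function(arr, axis, by, fill = 0) {
  n <- dim(arr)[axis]
  idx <- seq_len(n) + by
  ok <- idx >= 1L & idx <= n
  out <- array(fill, dim(arr))
  src <- idx[ok]
  dst <- seq_len(n)[ok]
  switch(axis,
         out[dst, , ] <- arr[src, , , drop = FALSE],
         out[, dst, ] <- arr[, src, , drop = FALSE],
         out[, , dst] <- arr[, , src, drop = FALSE])
  out
}

# Majority (median) filter over the ball neighbourhood, background padding.
morph_median <- function(arr, r) {
  offs <- ball_offsets(r)
  cnt <- array(0L, dim(arr))
  a <- array(as.integer(arr), dim(arr))
  for (i in seq_len(nrow(offs))) {
    s <- a
    if (offs$dx[i] != 0) s <- shift_zero(s, 1L, offs$dx[i])
    if (offs$dy[i] != 0) s <- shift_zero(s, 2L, offs$dy[i])
    if (offs$dz[i] != 0) s <- shift_zero(s, 3L, offs$dz[i])
    cnt <- cnt + s
  }
  array(cnt > nrow(offs) / 2, dim(arr))
}

#' Morphological cleaning of a binary mask
#'
#' Applies an ordered plan of morphological operations with a discrete ball
#' structuring element: `median(r)` (majority filter), `fill_holes`
#' (interior cavities become foreground), `open(r)` (erosion then dilation)
#' and `close(r)` (dilation then erosion). Out-of-grid voxels count as
#' background. An empty result is returned with a warning, not an error.
#'
#' @param mask a `mask3d`.
#' @param plan list of steps; each step is either a string (`"fill_holes"`)
#'   or a list `list(op = "median"|"open"|"close", r = radius)`, radius in
#'   voxels (>= 1).
#' @return a cleaned `mask3d` with updated provenance.
#' @export
morph_clean <- function(mask, plan) {
  arr <- mask$data
  prov <- mask$provenance
  for (step in plan) {
    if (is.character(step)) step <- list(op = step)
    op <- step$op
    r <- step$r
    if (op != "fill_holes") {
      if (is.null(r) || r < 1) stop("operation '", op, "' needs radius r >= 1")
    }
    arr <- switch(op,
      median = morph_median(arr, r),
      fill_holes = array(fill_holes_cpp(arr, dim(arr)), dim(arr)),
      open = morph_dilate(morph_erode(arr, r), r),
      close = morph_erode(morph_dilate(arr, r), r),
      stop("unknown morphological operation: ", op))
    prov <- c(prov, if (op == "fill_holes") "fill_holes"
                    else sprintf("%s(r=%g)", op, r))
  }
  if (!any(arr)) warning("morphological plan produced an empty mask")
  mask3d(arr, mask$voxel_size, mask$axes, provenance = prov)
}

#' Euclidean distance map of a mask
#'
#' Each foreground voxel carries the Euclidean distance, in micrometres, to
#' the nearest background voxel (voxel-centre metric); background voxels
#' carry 0. The grid border is treated as background, so the map of an
#' all-foreground grid grows from the faces inward.
#'
#' @param mask a non-empty `mask3d`.
#' @return a `volume3d` of distances (micrometres).
#' @export
euclidean_distance_map <- function(mask) {
  if (!any(mask$data)) stop("mask is empty")
  d <- dim(mask$data)
  big <- array(FALSE, d + 2L)
  big[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3])] <- mask$data
  d2 <- array(edt_sq_cpp(big, dim(big)), dim(big))
  out <- d2[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3])]
  volume3d(sqrt(out) * mask$voxel_size, mask$voxel_size, mask$axes)
}
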