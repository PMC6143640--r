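#' Resample a volume into slices perpendicular to a direction
#'
#' Builds a stack of planar slices orthogonal to `direction`, spaced one
#' voxel apart, with pixel size equal to the voxel size, by trilinear
#' interpolation; directions aligned with a grid axis bypass interpolation
#' and return the raw planes exactly. Masks are interpolated as 0/1 and
#' re-binarised at 0.5.
#'
#' @param x a `volume3d` or `mask3d`.
#' @param direction unit 3-vector (slice normal = mean fibre direction).
#' @return object of class `slice_stack`: `slices` (list of matrices, or
#'   logical matrices for masks), `pixel_size`, `spacing`, and the slice
#'   `frame` (`dir`, in-plane axes `e1`, `e2`, offsets) mapping pixel
#'   (i, j) of slice k to physical coordinates.
#' @export
resample_perpendicular <- function(x, direction) {
  direction <- direction / sqrt(sum(direction^2))
  vs <- x$voxel_size
  arr <- if (inherits(x, "mask3d")) array(as.numeric(x$data), dim(x$data))
         else x$data
  d <- dim(arr)
  ax <- which(abs(abs(direction) - 1) < 1e-9)
  if (length(ax) == 1L) {          # axis-aligned: exact planes
    perm <- switch(ax, c(2L, 3L, 1L), c(1L, 3L, 2L), c(1L, 2L, 3L))
    a2 <- aperm(arr, perm)
    slices <- lapply(seq_len(dim(a2)[3]), function(k) a2[, , k])
    e1 <- diag(3)[, perm[1]]; e2 <- diag(3)[, perm[2]]
    frame <- list(dir = abs(direction), e1 = e1, e2 = e2,
                  s0 = 0, a0 = 0, b0 = 0)
  } else {
    ext <- (d - 1) * vs
    corners <- as.matrix(expand.grid(c(0, ext[1]), c(0, ext[2]),
                                     c(0, ext[3])))
    fr <- transverse_frame(direction)
    e1 <- fr$n1; e2 <- fr$n2
    s_rng <- range(corners %*% direction)
    a_rng <- range(corners %*% e1)
    b_rng <- range(corners %*% e2)
    s_pos <- seq(s_rng[1], s_rng[2], by = vs)
    a_pos <- seq(a_rng[1], a_rng[2], by = vs)
    b_pos <- seq(b_rng[1], b_rng[2], by = vs)
    ab <- as.matrix(expand.grid(a = a_pos, b = b_pos))
    base <- ab[, 1] %o% e1 + ab[, 2] %o% e2
    slices <- lapply(s_pos, function(s) {
      pts <- sweep(base, 2, s * direction, "+") / vs
      matrix(trilinear(arr, pts), nrow = length(a_pos))
    })
    frame <- list(dir = direction, e1 = e1, e2 = e2,
                  s0 = s_rng[1], a0 = a_rng[1], b0 = b_rng[1])
  }
  if (inherits(x, "mask3d"))
    slices <- lapply(slices, function(m) m > 0.5)
  structure(list(slices = slices, pixel_size = vs, spacing = vs,
                 frame = frame, is_mask = inherits(x, "mask3d")),
            class = "slice_stack")
}

# Vectorised trilinear interpolation at voxel-space points (0-based
# continuous coordinates); points outside the grid return `fill`.
trilinear <- function(arr, pts, fill = 0) {
  d <- dim(arr)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  inside <- x >= 0 & y >= 0 & z >= 0 &
            x <= d[1] - 1 & y <= d[2] - 1 & z <= d[3] - 1
  out <- rep(fill, nrow(pts))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  x0 <- pmin(floor(x), d[1] - 2); y0 <- pmin(floor(y), d[2] - 2)
  z0 <- pmin(floor(z), d[3] - 2)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(i, j, k) arr[cbind(i + 1, j + 1, k + 1)]
  val <- (1 - fx) * (1 - fy) * (1 - fz) * at(x0, y0, z0) +
         fx * (1 - fy) * (1 - fz) * at(x0 + 1, y0, z0) +
         (1 - fx) * fy * (1 - fz) * at(x0, y0 + 1, z0) +
         fx * fy * (1 - fz) * at(x0 + 1, y0 + 1, z0) +
         (1 - fx) * (1 - fy) * fz * at(x0, y0, z0 + 1) +
         fx * (1 - fy) * fz * at(x0 + 1, y0, z0 + 1) +
         (1 - fx) * fy * fz * at(x0, y0 + 1, z0 + 1) +
         fx * fy * fz * at(x0 + 1, y0 + 1, z0 + 1)
  out[inside] <- val
  out
}

# 2D separable Gaussian smoothing of a matrix, mirror padding.
smooth2d <- function(m, sigma, radius = ceiling(3 * sigma)) {
  k <- gauss_kernel(sigma, radius)
  sh <- function(mm, axis, by) {
    n <- dim(mm)[axis]
    idx <- seq_len(n) + by
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    idx <- ifelse(idx > n, 2L * n - idx, idx)
    idx <- pmax(1L, pmin(n, idx))
    if (axis == 1) mm[idx, , drop = FALSE] else mm[, idx, drop = FALSE]
  }
  for (axis in 1:2) {
    out <- matrix(0, nrow(m), ncol(m))
    r <- (length(k) - 1) / 2
    for (o in seq_along(k)) out <- out + k[o] * sh(m, axis, o - 1 - r)
    m <- out
  }
  m
}

# Sub-pixel perimeter: total length of the 0.5-level iso-contours of the
# lightly smoothed indicator image. Pixel-edge counting would inflate the
# perimeter of a disc by ~27% and make circular fibres look ragged
# (xi ~ 0.6); the smoothed sub-pixel contour tracks the true boundary to
# a few percent for discs above ~15 px diameter.
region_perimeter <- function(ind, pixel_size, sigma = 1.0) {
  pad <- ceiling(3 * sigma) + 1L
  big <- matrix(0, nrow(ind) + 2 * pad, ncol(ind) + 2 * pad)
  big[pad + seq_len(nrow(ind)), pad + seq_len(ncol(ind))] <- ind
  sm <- smooth2d(big, sigma)
  cl <- contourLines(x = seq_len(nrow(big)), y = seq_len(ncol(big)),
                     z = sm, levels = 0.5)
  if (!length(cl)) return(0)
  per <- 0
  for (cc in cl) {
    xs <- c(cc$x, cc$x[1]); ys <- c(cc$y, cc$y[1])
    per <- per + sum(sqrt(diff(xs)^2 + diff(ys)^2))
  }
  per * pixel_size
}

#' Detect fibre cross-sections in a binary slice
#'
#' One section per 8-connected foreground region of at least `min_area_px`
#' pixels. For each: boundary perimeter `P` (sub-pixel iso-contour length
#' at level 0.5), area (pixel count times pixel area), equivalent diameter
#' `d_e = sqrt(4 area / pi)`, roundness `xi = 4 pi area / P^2` (1 for a
#' circle) and the area centroid `x_G`. An empty slice yields an empty
#' table.
#'
#' @param slice logical matrix (a binary slice).
#' @param pixel_size pixel edge (micrometres).
#' @param min_area_px minimal region area in pixels (default 9).
#' @return data.frame with columns `label`, `n_px`, `area`, `perimeter`,
#'   `d_e`, `xi`, `cu`, `cv` (in-slice centroid, micrometres, 0-based).
#' @export
detect_sections <- function(slice, pixel_size = 1, min_area_px = 9L) {
  stopifnot(is.matrix(slice), is.logical(slice))
  d3 <- c(dim(slice), 1L)
  lab <- array(label_components_cpp(as.vector(slice), d3, 26L), dim(slice))
  labs <- setdiff(unique(as.vector(lab)), 0L)
  rows <- list()
  for (l in labs) {
    idx <- which(lab == l, arr.ind = TRUE)
    if (nrow(idx) < min_area_px) next
    area <- nrow(idx) * pixel_size^2
    pad <- 2L
    i_rng <- range(idx[, 1]); j_rng <- range(idx[, 2])
    sub <- matrix(0, diff(i_rng) + 1 + 2 * pad, diff(j_rng) + 1 + 2 * pad)
    sub[cbind(idx[, 1] - i_rng[1] + 1 + pad,
              idx[, 2] - j_rng[1] + 1 + pad)] <- 1
    P <- region_perimeter(sub, pixel_size)
    rows[[length(rows) + 1]] <- data.frame(
      label = l, n_px = nrow(idx), area = area, perimeter = P,
      d_e = sqrt(4 * area / pi), xi = 4 * pi * area / P^2,
      cu = (mean(idx[, 1]) - 1) * pixel_size,
      cv = (mean(idx[, 2]) - 1) * pixel_size)
  }
  if (!length(rows))
    return(data.frame(label = integer(), n_px = integer(), area = numeric(),
                      perimeter = numeric(), d_e = numeric(), xi = numeric(),
                      cu = numeric(), cv = numeric()))
  do.call(rbind, rows)
}

#' Detect sections across a whole slice stack
#'
#' Runs [detect_sections()] on every slice and appends the slice index and
#' the 3D physical centroid reconstructed from the stack geometry.
#'
#' @param stack a `slice_stack` of a mask.
#' @param min_area_px minimal region area in pixels.
#' @return data.frame as [detect_sections()] plus `slice`, `x`, `y`, `z`.
#' @export
sections_from_stack <- function(stack, min_area_px = 9L) {
  fr <- stack$frame
  out <- list()
  for (k in seq_along(stack$slices)) {
    df <- detect_sections(stack$slices[[k]], stack$pixel_size, min_area_px)
    if (!nrow(df)) next
    df$slice <- k
    s <- fr$s0 + (k - 1) * stack$spacing
    xyz <- t(sapply(seq_len(nrow(df)), function(r)
      s * fr$dir + (fr$a0 + df$cu[r]) * fr$e1 + (fr$b0 + df$cv[r]) * fr$e2))
    df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
    out[[length(out) + 1]] <- df
  }
  if (!length(out))
    return(cbind(detect_sections(matrix(FALSE, 2, 2), 1),
                 data.frame(slice = integer(), x = numeric(), y = numeric(),
                            z = numeric())))
  do.call(rbind, out)
}

#' Link sections into fibre tracks across slices
#'
#' Greedy mutual-nearest-centroid linking between consecutive slices: two
#' sections are linked iff each is the other's nearest in-plane neighbour
#' and their centroid distance is at most `max_jump`. Ties are broken by
#' smaller distance then smaller label. With `max_jump = 0` every section
#' is a singleton track.
#'
#' @param sections data.frame from [sections_from_stack()] (needs at least
#'   2 distinct slices for links to form).
#' @param max_jump maximal in-plane centroid jump (micrometres).
#' @return list of tracks; each track is a list with `rows` (row indices
#'   into `sections`), `centroids` (n x 3, micrometres) and unit mean
#'   `tangent` (NA for singletons).
#' @export
link_tracks <- function(sections, max_jump) {
  n <- nrow(sections)
  track_id <- rep(NA_integer_, n)
  next_id <- 0L
  slices <- sort(unique(sections$slice))
  for (si in seq_along(slices)) {
    cur <- which(sections$slice == slices[si])
    for (r in cur) if (is.na(track_id[r])) { next_id <- next_id + 1L
                                             track_id[r] <- next_id }
    if (si == length(slices)) break
    if (slices[si + 1] != slices[si] + 1) next
    nxt <- which(sections$slice == slices[si + 1])
    if (!length(cur) || !length(nxt) || max_jump <= 0) next
    dmat <- outer(sections$cu[cur], sections$cu[nxt], "-")^2 +
            outer(sections$cv[cur], sections$cv[nxt], "-")^2
    dmat <- sqrt(dmat)
    for (a in order(sections$label[cur])) {
      j <- which.min(dmat[a, ])
      if (dmat[a, j] > max_jump) next
      if (which.min(dmat[, j]) != a) next
      track_id[nxt[j]] <- track_id[cur[a]]
    }
  }
  tracks <- list()
  for (id in unique(track_id)) {
    rows <- which(track_id == id)
    rows <- rows[order(sections$slice[rows])]
    cen <- as.matrix(sections[rows, c("x", "y", "z")])
    tangent <- if (nrow(cen) >= 2) {
      t0 <- cen[nrow(cen), ] - cen[1, ]
      t0 / sqrt(sum(t0^2))
    } else rep(NA_real_, 3)
    tracks[[length(tracks) + 1]] <- list(rows = rows, centroids = cen,
                                         tangent = tangent, id = id)
  }
  tracks
}

#' Discard tracks misaligned with the main fibre direction
#'
#' A track is discarded iff the (axial) angle between its mean tangent and
#' `main_direction` exceeds `alpha_max` degrees. Singleton tracks (no
#' tangent) are kept. Both sets are returned, with the measured angles.
#'
#' @param tracks output of [link_tracks()].
#' @param main_direction unit 3-vector.
#' @param alpha_max misalignment threshold in degrees (default 30).
#' @return list with `kept`, `discarded` (lists of tracks, each annotated
#'   with `$angle` in degrees).
#' @export
misalignment_filter <- function(tracks, main_direction, alpha_max = 30) {
  md <- main_direction / sqrt(sum(main_direction^2))
  kept <- list(); discarded <- list()
  for (tr in tracks) {
    if (any(is.na(tr$tangent))) { tr$angle <- NA_real_
                                  kept[[length(kept) + 1]] <- tr; next }
    ang <- acos(pmin(1, abs(sum(tr$tangent * md)))) * 180 / pi
    tr$angle <- ang
    if (ang > alpha_max) discarded[[length(discarded) + 1]] <- tr
    else kept[[length(kept) + 1]] <- tr
  }
  list(kept = kept, discarded = discarded)
}

# Mode of a histogram with Freedman-Diaconis bin width; robust "peak
# value" of a skewed distribution.
fd_mode <- function(x) {
  if (length(unique(x)) == 1) return(x[1])
  bw <- 2 * diff(quantile(x, c(0.25, 0.75), names = FALSE)) /
        length(x)^(1 / 3)
  if (bw <= 0) return(median(x))
  breaks <- seq(min(x) - bw / 2, max(x) + bw, by = bw)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                nbins = length(breaks) - 1)
  centres <- (breaks[-1] + breaks[-length(breaks)]) / 2
  centres[which.max(h)]
}

#' Surface number density and section-shape statistics
#'
#' Summarises a section table: surface number density (mean number of
#' sections per slice divided by the slice area, per square millimetre)
#' and the distributions of equivalent diameter and roundness, reported as
#' histogram mode ("peak", Freedman-Diaconis binning) and median. The
#' full per-section table is retained.
#'
#' @param sections data.frame from [sections_from_stack()] (non-empty).
#' @param slice_area_mm2 analysed slice area in square millimetres.
#' @return list: `density_mm2`, `d_e_peak`, `d_e_median`, `xi_peak`,
#'   `xi_median`, `n_sections`, `n_slices`, `table`.
#' @export
density_and_stats <- function(sections, slice_area_mm2) {
  if (!nrow(sections)) stop("no sections to summarise")
  per_slice <- tabulate(factor(sections$slice))
  list(density_mm2 = mean(per_slice) / slice_area_mm2,
       d_e_peak = fd_mode(sections$d_e),
       d_e_median = median(sections$d_e),
       xi_peak = fd_mode(sections$xi),
       xi_median = median(sections$xi),
       n_sections = nrow(sections),
       n_slices = length(per_slice),
       table = sections)
}

#' Morphometric profile along a single fibre
#'
#' Measures the cross-section of one fibre in planes orthogonal to the
#' local tangent of its centreline, sampled along arc length. The
#' centreline is either provided (n x 3 matrix, micrometres) or derived by
#' tracking the section centroids along the fibre's principal axis; a
#' branching fibre (more than one section in a perpendicular slice) is an
#' error listing the offending slices.
#'
#' @param mask a `mask3d` containing a single fibre.
#' @param centreline optional n x 3 matrix of centreline points.
#' @param patch_half_width half-width of the sampled perpendicular patch
#'   (micrometres); default three times the largest inscribed radius.
#' @return list: `profile` (data.frame `arc`, `d_e`, `xi`), `d_e_mean`,
#'   `d_e_range`, `xi_mean`, `xi_range`, `centreline`.
#' @export
single_fibre_profile <- function(mask, centreline = NULL,
                                 patch_half_width = NULL) {
  vs <- mask$voxel_size
  if (is.null(centreline)) {
    idx <- which(mask$data, arr.ind = TRUE)
    pts <- (idx - 1) * vs
    pc <- prcomp(pts, center = TRUE)
    axis0 <- pc$rotation[, 1]
    stk <- resample_perpendicular(mask, axis0)
    secs <- sections_from_stack(stk, min_area_px = 5L)
    multi <- as.integer(names(which(table(secs$slice) > 1)))
    if (length(multi))
      stop("branching fibre: multiple sections in slices ",
           paste(multi, collapse = ", "))
    secs <- secs[order(secs$slice), ]
    centreline <- as.matrix(secs[, c("x", "y", "z")])
  }
  if (nrow(centreline) < 10) stop("centreline too short (need >= 10 points)")
  # light smoothing of the centreline to stabilise tangents
  smooth_col <- function(v) as.vector(stats::filter(v, rep(1 / 5, 5),
                                                    sides = 2))
  cs <- apply(centreline, 2, smooth_col)
  keep <- !is.na(cs[, 1])
  cs <- cs[keep, , drop = FALSE]
  arc <- c(0, cumsum(sqrt(rowSums(diff(cs)^2))))
  if (is.null(patch_half_width)) {
    ed <- euclidean_distance_map(mask)
    patch_half_width <- 3 * max(ed$data) + 2 * vs
  }
  arr <- array(as.numeric(mask$data), dim(mask$data))
  grid1 <- seq(-patch_half_width, patch_half_width, by = vs)
  ab <- as.matrix(expand.grid(a = grid1, b = grid1))
  np <- length(grid1)
  centre_px <- which.min(abs(grid1))
  rows <- list()
  for (i in seq_len(nrow(cs))) {
    i0 <- max(1, i - 1); i1 <- min(nrow(cs), i + 1)
    tg <- cs[i1, ] - cs[i0, ]
    tg <- tg / sqrt(sum(tg^2))
    fr <- transverse_frame(tg)
    pts <- sweep(ab[, 1] %o% fr$n1 + ab[, 2] %o% fr$n2, 2, cs[i, ], "+") / vs
    sl <- matrix(trilinear(arr, pts), nrow = np) > 0.5
    lab <- array(label_components_cpp(as.vector(sl), c(np, np, 1L), 26L),
                 dim(sl))
    l0 <- lab[centre_px, centre_px]
    if (l0 == 0) next
    df <- detect_sections(sl & (lab == l0), vs, min_area_px = 5L)
    if (nrow(df) != 1) next
    rows[[length(rows) + 1]] <- data.frame(arc = arc[i], d_e = df$d_e,
                                           xi = df$xi)
  }
  prof <- do.call(rbind, rows)
  if (is.null(prof) || nrow(prof) < 3)
    stop("could not measure sections along the centreline")
  list(profile = prof,
       d_e_mean = mean(prof$d_e), d_e_range = range(prof$d_e),
       xi_mean = mean(prof$xi), xi_range = range(prof$xi),
       centreline = cs)
}
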