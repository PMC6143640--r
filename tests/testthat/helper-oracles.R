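# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (direct definitions, explicit loops) so they cannot
# share a defect with the package's optimised kernels.

# physical voxel-centre coordinates of every voxel, 0-based, unit spacing
vox_coords <- function(d) {
  as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                        z = 0:(d[3] - 1)))
}

# Distance (voxel units) from each foreground voxel to the nearest
# background voxel, the grid border counting as background. Background
# voxels map to 0.
bf_edt <- function(arr) {
  d <- dim(arr)
  big <- array(FALSE, d + 2L)
  big[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3])] <- arr
  co <- vox_coords(dim(big))
  fg <- which(big)
  bg <- which(!big)
  out <- array(0, dim(big))
  bgco <- co[bg, , drop = FALSE]
  for (i in fg) {
    dd <- (bgco[, 1] - co[i, 1])^2 + (bgco[, 2] - co[i, 2])^2 +
          (bgco[, 3] - co[i, 3])^2
    out[i] <- sqrt(min(dd))
  }
  out[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3]),
      drop = FALSE]
}

bf_ball <- function(r) {
  s <- (-floor(r)):floor(r)
  g <- as.matrix(expand.grid(s, s, s))
  g[rowSums(g^2) <= r^2, , drop = FALSE]
}

# out-of-grid voxels are background for both operations
bf_dilate <- function(arr, r) {
  d <- dim(arr)
  offs <- bf_ball(r)
  out <- array(FALSE, d)
  idx <- which(arr, arr.ind = TRUE)
  for (k in seq_len(nrow(idx)))
    for (o in seq_len(nrow(offs))) {
      p <- idx[k, ] + offs[o, ]
      if (all(p >= 1) && all(p <= d)) out[p[1], p[2], p[3]] <- TRUE
    }
  out
}

bf_erode <- function(arr, r) {
  d <- dim(arr)
  offs <- bf_ball(r)
  out <- array(FALSE, d)
  idx <- which(arr, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    ok <- TRUE
    for (o in seq_len(nrow(offs))) {
      p <- idx[k, ] + offs[o, ]
      if (any(p < 1) || any(p > d) || !arr[p[1], p[2], p[3]]) {
        ok <- FALSE; break
      }
    }
    if (ok) out[idx[k, 1], idx[k, 2], idx[k, 3]] <- TRUE
  }
  out
}

# Exhaustive maximal-inscribed-sphere thickness (voxel units, diameter):
# sphere centred at c with radius = its border-aware EDT covers x iff
# |x - c| < r(c); thickness(x) = 2 max over covering spheres.
bf_local_thickness <- function(arr) {
  d <- dim(arr)
  ed <- bf_edt(arr)
  fg <- which(arr)
  co <- vox_coords(d)
  out <- array(0, d)
  r <- ed[fg]
  fco <- co[fg, , drop = FALSE]
  for (k in seq_along(fg)) {
    dd <- sqrt((fco[, 1] - fco[k, 1])^2 + (fco[, 2] - fco[k, 2])^2 +
               (fco[, 3] - fco[k, 3])^2)
    out[fg[k]] <- 2 * max(r[dd < r])
  }
  out
}

# seeded random blob-ish mask (thresholded smoothed noise)
rand_mask <- function(d, seed, p = 0.5) {
  set.seed(seed)
  raw <- array(runif(prod(d)), d)
  k <- c(0.25, 0.5, 0.25)
  sm <- raw
  for (ax in 1:3) {
    lo <- sm; hi <- sm
    n <- d[ax]
    idx_lo <- c(1, seq_len(n - 1)); idx_hi <- c(seq_len(n - 1) + 1, n)
    if (ax == 1) { lo <- sm[idx_lo, , , drop = FALSE]
                   hi <- sm[idx_hi, , , drop = FALSE] }
    if (ax == 2) { lo <- sm[, idx_lo, , drop = FALSE]
                   hi <- sm[, idx_hi, , drop = FALSE] }
    if (ax == 3) { lo <- sm[, , idx_lo, drop = FALSE]
                   hi <- sm[, , idx_hi, drop = FALSE] }
    sm <- k[1] * lo + k[2] * sm + k[3] * hi
  }
  sm > quantile(sm, 1 - p)
}

disc_slice <- function(r, n = ceiling(2 * r) + 11) {
  xs <- row(matrix(0, n, n)) - (n + 1) / 2
  ys <- col(matrix(0, n, n)) - (n + 1) / 2
  xs^2 + ys^2 <= r^2
}

square_slice <- function(a, pad = 6) {
  n <- a + 2 * pad
  m <- matrix(FALSE, n, n)
  m[pad + seq_len(a), pad + seq_len(a)] <- TRUE
  m
}

# 90-degree grid rotations: volume operator and matching rotation matrix
rot90_z <- function(arr) {
  n <- dim(arr)[1]
  aperm(arr, c(2, 1, 3))[n:1, , , drop = FALSE]
}
R_z <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
rot90_x <- function(arr) {
  n <- dim(arr)[2]
  aperm(arr, c(1, 3, 2))[, n:1, , drop = FALSE]
}
R_x <- matrix(c(1, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3)
rot90_y <- function(arr) {
  n <- dim(arr)[3]
  aperm(arr, c(3, 2, 1))[, , n:1, drop = FALSE]
}
R_y <- matrix(c(0, 0, -1, 0, 1, 0, 1, 0, 0), 3, 3)

# straight-cylinder A recovery path used by several tests
recover_A <- function(vol, w = 9, min_coherence = 0.2) {
  m <- threshold_volume(vol, "otsu")
  dm <- euclidean_distance_map(m)
  st <- structure_tensor_field(grey_gradient(vol), w)
  orientation_field(st, m, dm, min_coherence = min_coherence)
}

make_bead_set <- function(coords) {
  coords <- as.matrix(coords)
  structure(list(beads = data.frame(label = seq_len(nrow(coords)),
                                    x = coords[, 1], y = coords[, 2],
                                    z = coords[, 3],
                                    volume_um3 = rep(1, nrow(coords))),
                 threshold = NA),
            class = "bead_set")
}
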