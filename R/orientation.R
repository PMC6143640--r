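#' Grey-level gradient by centred finite differences
#'
#' Gradient of the intensity with respect to physical position
#' (intensity per micrometre), computed with a centred difference scheme at
#' interior voxels and mirror padding at the boundary (which makes the
#' boundary-normal component vanish there).
#'
#' @param volume a `volume3d` with at least 3 voxels per axis.
#' @return list with components `gx`, `gy`, `gz` (arrays) and `voxel_size`.
#' @export
grey_gradient <- function(volume) {
  if (any(dim(volume$data) < 3))
    stop("gradient needs at least 3 voxels per axis")
  v <- volume$data
  h <- 2 * volume$voxel_size
  list(gx = (shift_mirror(v, 1L, 1L) - shift_mirror(v, 1L, -1L)) / h,
       gy = (shift_mirror(v, 2L, 1L) - shift_mirror(v, 2L, -1L)) / h,
       gz = (shift_mirror(v, 3L, 1L) - shift_mirror(v, 3L, -1L)) / h,
       voxel_size = volume$voxel_size)
}

#' Per-voxel 3D structure tensor field
#'
#' At each voxel, the Gaussian-weighted local average of the gradient outer
#' product over a window of lateral size `w` voxels: the Gaussian has
#' sigma = w/6 (so the window spans +/- 3 sigma) and is truncated at the
#' window. Each tensor is symmetric positive semi-definite by construction.
#' Presets matching typical acquisitions: `w = 21` for medium-resolution
#' fibre bundles, `w = 17` or `21` for high-resolution fibres.
#'
#' @param gradient output of [grey_gradient()].
#' @param w odd window size in voxels (>= 3, at most the grid extent).
#' @return list of the six component arrays `sxx, syy, szz, sxy, sxz, syz`,
#'   plus `w` and `voxel_size`.
#' @export
structure_tensor_field <- function(gradient, w = 17L) {
  if (w %% 2 == 0 || w < 3) stop("window size w must be odd and >= 3")
  if (any(dim(gradient$gx) < w)) stop("window w larger than the grid")
  sigma <- w / 6
  radius <- (w - 1L) / 2L
  sm <- function(a) smooth_gauss(a, sigma, radius)
  list(sxx = sm(gradient$gx * gradient$gx),
       syy = sm(gradient$gy * gradient$gy),
       szz = sm(gradient$gz * gradient$gz),
       sxy = sm(gradient$gx * gradient$gy),
       sxz = sm(gradient$gx * gradient$gz),
       syz = sm(gradient$gy * gradient$gz),
       w = as.integer(w), voxel_size = gradient$voxel_size)
}

# Canonical representative of an axial direction: flip p so that p_y >= 0;
# if p_y = 0 require p_x >= 0; if p_x = p_y = 0 require p_z >= 0. Makes
# (theta, phi) unique with theta in [0, 180] and phi in [0, 180).
canonicalize_axial <- function(p) {
  flip <- p[, 2] < 0 |
    (p[, 2] == 0 & p[, 1] < 0) |
    (p[, 2] == 0 & p[, 1] == 0 & p[, 3] < 0)
  p[flip, ] <- -p[flip, , drop = FALSE]
  p
}

#' Fibre angles of a unit axial vector
#'
#' Expresses an axial unit vector in the anatomical frame as
#' `p = sin(theta) cos(phi) e_x + sin(theta) sin(phi) e_y + cos(theta) e_z`
#' with `theta` in \[0, 180\] degrees (angle to e_z) and `phi` in
#' \[0, 180) degrees (angle of the in-plane projection to e_x). The
#' antipodal representative is canonicalised first, so `p` and `-p` map to
#' the same angles; at the pole (p parallel to e_z) `phi = 0` by
#' convention.
#'
#' @param p unit 3-vector or n x 3 matrix of unit rows.
#' @return data.frame with columns `theta`, `phi` (degrees).
#' @export
angles_from_vector <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, 1)
  nrm <- sqrt(rowSums(p^2))
  if (any(nrm < 1e-12)) stop("zero vector has no direction")
  if (any(abs(nrm - 1) > 1e-6)) stop("vectors must be unit length")
  p <- canonicalize_axial(p / nrm)
  theta <- acos(pmin(1, pmax(-1, p[, 3]))) * 180 / pi
  phi <- atan2(p[, 2], p[, 1]) * 180 / pi
  phi[p[, 1] == 0 & p[, 2] == 0] <- 0
  data.frame(theta = theta, phi = phi)
}

#' Per-voxel fibre orientation field
#'
#' Extracts the minor eigenvector `p_i` (smallest eigenvalue) of each
#' structure tensor: for an elongated texture it points along the fibre.
#' A voxel is valid iff it lies inside the fibre mask, deeper than
#' `min_depth` according to the distance map (boundary voxels see the
#' interface, not the texture), has coherence
#' `c = 1 - mu3/mu1 >= min_coherence`, and has a well-separated minor
#' eigenvalue pair (relative gap of mu2 and mu3 above 1e-9). Invalid
#' voxels are excluded from every downstream statistic.
#'
#' @param tensors output of [structure_tensor_field()].
#' @param mask optional `mask3d` restricting analysis to the fibrous phase.
#' @param distance_map optional `volume3d` from [euclidean_distance_map()].
#' @param min_depth minimum distance-map value (micrometres) for validity;
#'   default one voxel.
#' @param min_coherence coherence gate in \[0, 1\] (default 0.2).
#' @return an object of class `orientation_field`: arrays `px, py, pz`
#'   (canonical unit vector), `theta`, `phi` (degrees), `coherence`,
#'   logical `valid`, plus `w` and `voxel_size`.
#' @export
orientation_field <- function(tensors, mask = NULL, distance_map = NULL,
                              min_depth = NULL, min_coherence = 0.2) {
  d <- dim(tensors$sxx)
  vs <- tensors$voxel_size
  if (is.null(min_depth)) min_depth <- vs
  cand <- array(TRUE, d)
  if (!is.null(mask)) {
    if (!identical(dim(mask$data), d)) stop("mask grid not congruent")
    cand <- cand & mask$data
  }
  if (!is.null(distance_map)) {
    if (!identical(dim(distance_map$data), d))
      stop("distance map grid not congruent")
    cand <- cand & (distance_map$data >= min_depth)
  }
  idx <- which(cand)
  out <- list(px = array(NA_real_, d), py = array(NA_real_, d),
              pz = array(NA_real_, d), theta = array(NA_real_, d),
              phi = array(NA_real_, d), coherence = array(NA_real_, d),
              valid = array(FALSE, d), w = tensors$w, voxel_size = vs)
  class(out) <- "orientation_field"
  if (!length(idx)) return(out)
  S <- cbind(tensors$sxx[idx], tensors$syy[idx], tensors$szz[idx],
             tensors$sxy[idx], tensors$sxz[idx], tensors$syz[idx])
  eg <- minor_eigs_cpp(S)
  mu <- eg$mu
  ok <- mu[, 1] > 0
  coh <- rep(NA_real_, length(idx))
  coh[ok] <- 1 - mu[ok, 3] / mu[ok, 1]
  nondeg <- ok & (mu[, 2] - mu[, 3]) > 1e-9 * pmax(mu[, 1], 1e-300)
  valid <- nondeg & !is.na(coh) & coh >= min_coherence
  p <- canonicalize_axial(eg$p)
  ang <- angles_from_vector(p[valid, , drop = FALSE])
  vi <- idx[valid]
  out$px[vi] <- p[valid, 1]; out$py[vi] <- p[valid, 2]
  out$pz[vi] <- p[valid, 3]
  out$theta[vi] <- ang$theta; out$phi[vi] <- ang$phi
  out$coherence[idx] <- coh
  out$valid[vi] <- TRUE
  out
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("<orientation_field> %s voxels, %d valid, window w = %d\n",
              paste(dim(x$valid), collapse = " x "), sum(x$valid), x$w))
  invisible(x)
}

valid_vectors <- function(field) {
  v <- which(field$valid)
  cbind(field$px[v], field$py[v], field$pz[v])
}

#' Second-order fibre orientation tensor
#'
#' The first non-zero moment of the orientation distribution:
#' `A = (1/N) sum_i p_i (x) p_i` over the `N` valid voxels. `A` is
#' symmetric, positive semi-definite and has unit trace; its diagonal
#' dominance encodes the anisotropy of the network (transverse isotropy:
#' two equal minor eigenvalues; orthotropy: three distinct).
#'
#' @param x an `orientation_field`, or an n x 3 matrix of unit axial
#'   vectors.
#' @return an object of class `orientation_tensor`: 3 x 3 matrix `A`,
#'   sample count `N`, frame labels.
#' @export
orientation_tensor <- function(x) {
  p <- if (inherits(x, "orientation_field")) valid_vectors(x) else as.matrix(x)
  if (nrow(p) < 1) stop("no valid orientation samples")
  A <- crossprod(p) / nrow(p)
  structure(list(A = A, N = nrow(p), frame = c("x", "y", "z")),
            class = "orientation_tensor")
}

#' @export
print.orientation_tensor <- function(x, ...) {
  cat(sprintf("<orientation_tensor> N = %d, frame (%s)\n", x$N,
              paste(x$frame, collapse = ", ")))
  print(round(x$A, 4))
  invisible(x)
}

#' Planar (2D) second-order orientation tensor
#'
#' Projects each valid fibre vector onto the requested plane, renormalises,
#' discards voxels whose in-plane norm is below 1e-6 (fibres perpendicular
#' to the plane), and averages the planar outer products. The result has
#' unit trace by construction.
#'
#' @param x an `orientation_field` or n x 3 matrix of unit vectors.
#' @param plane character(2), the two anatomical axes of the plane
#'   (default `c("x", "y")`).
#' @return an `orientation_tensor` whose `A` is 2 x 2.
#' @export
orientation_tensor_2d <- function(x, plane = c("x", "y")) {
  p <- if (inherits(x, "orientation_field")) valid_vectors(x) else as.matrix(x)
  cols <- match(plane, c("x", "y", "z"))
  if (any(is.na(cols)) || length(cols) != 2) stop("invalid plane")
  q <- p[, cols, drop = FALSE]
  nrm <- sqrt(rowSums(q^2))
  q <- q[nrm >= 1e-6, , drop = FALSE] / nrm[nrm >= 1e-6]
  if (nrow(q) < 1) stop("all projections are degenerate for this plane")
  structure(list(A = crossprod(q) / nrow(q), N = nrow(q), frame = plane),
            class = "orientation_tensor")
}

#' Discrete orientation distribution function (ODF)
#'
#' 2D histogram of the fibre angles `(theta, phi)` over the valid voxels,
#' on a regular grid of `bin_width`-degree bins covering
#' \[0, 180\] x \[0, 180). Entries can optionally be weighted by coherence
#' or corrected for solid angle (divide by `sin(theta)`); both are off by
#' default (raw counts).
#'
#' @param field an `orientation_field`.
#' @param bin_width bin width in degrees; must divide 180.
#' @param weight `"none"` (raw counts) or `"coherence"`.
#' @param solid_angle apply a 1/sin(theta) solid-angle correction?
#' @return object of class `odf_histogram`: matrices `counts` and `freq`
#'   (frequencies sum to 1), bin centre vectors, `bin_width`.
#' @export
odf_histogram <- function(field, bin_width = 3, weight = c("none", "coherence"),
                          solid_angle = FALSE) {
  weight <- match.arg(weight)
  if (180 %% bin_width != 0) stop("bin width must divide 180 degrees")
  nb <- as.integer(180 / bin_width)
  v <- which(field$valid)
  th <- field$theta[v]; ph <- field$phi[v]
  it <- pmin(nb, floor(th / bin_width) + 1L)
  ip <- pmin(nb, floor(ph / bin_width) + 1L)
  wgt <- rep(1, length(v))
  if (weight == "coherence") wgt <- field$coherence[v]
  if (solid_angle) {
    cen <- (it - 0.5) * bin_width
    wgt <- wgt / pmax(sin(cen * pi / 180), 1e-3)
  }
  counts <- matrix(0, nb, nb)
  for (k in seq_along(v)) counts[it[k], ip[k]] <- counts[it[k], ip[k]] + wgt[k]
  structure(list(counts = counts, freq = counts / sum(counts),
                 theta_centres = (seq_len(nb) - 0.5) * bin_width,
                 phi_centres = (seq_len(nb) - 0.5) * bin_width,
                 bin_width = bin_width),
            class = "odf_histogram")
}

#' Peaks of an ODF histogram
#'
#' Local maxima of the lightly smoothed (3 x 3 box) histogram above
#' `rel_height` times its global maximum, suppressed greedily so retained
#' peaks are at least `min_separation` degrees apart (Euclidean distance
#' in angle space). Peaks lie on bin centres.
#'
#' @param hist an `odf_histogram`.
#' @param min_separation minimal angular separation between peaks (deg).
#' @param rel_height minimal height relative to the global maximum.
#' @return data.frame with columns `theta`, `phi` (degrees, bin centres)
#'   and `height` (frequency in the raw histogram).
#' @export
find_odf_peaks <- function(hist, min_separation = 15, rel_height = 0.5) {
  cm <- hist$counts
  nb <- nrow(cm)
  pad <- matrix(0, nb + 2, nb + 2)
  pad[2:(nb + 1), 2:(nb + 1)] <- cm
  sm <- matrix(0, nb, nb)
  for (di in -1:1) for (dj in -1:1)
    sm <- sm + pad[(2:(nb + 1)) + di, (2:(nb + 1)) + dj]
  sm <- sm / 9
  thr <- rel_height * max(sm)
  is_peak <- matrix(TRUE, nb, nb)
  padl <- matrix(-Inf, nb + 2, nb + 2)
  padl[2:(nb + 1), 2:(nb + 1)] <- sm
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_peak <- is_peak & (sm >= padl[(2:(nb + 1)) + di, (2:(nb + 1)) + dj])
  }
  cand <- which(is_peak & sm >= thr & sm > 0, arr.ind = TRUE)
  if (!nrow(cand)) return(data.frame(theta = numeric(), phi = numeric(),
                                     height = numeric()))
  hgt <- sm[cand]
  # ties on the smoothed surface are resolved by the raw counts
  ord <- order(-hgt, -cm[cand], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  th <- hist$theta_centres[cand[, 1]]
  ph <- hist$phi_centres[cand[, 2]]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    dsep <- sqrt((th[i] - th[keep])^2 + (ph[i] - ph[keep])^2)
    if (all(dsep >= min_separation)) keep[i] <- TRUE
  }
  data.frame(theta = th[keep], phi = ph[keep],
             height = hist$freq[cand[keep, , drop = FALSE]])
}

#' Summary statistics of the fibre angles
#'
#' Arithmetic mean and standard deviation of `theta` and `phi` (degrees)
#' over the valid voxels; this matches the usual reporting convention for
#' angle dispersions of fibrous networks on \[0, 180\] degrees. A circular
#' (axial, double-angle) mode is available but off by default.
#'
#' @param field an `orientation_field` with at least 2 valid voxels.
#' @param circular use axial circular statistics instead of arithmetic?
#' @return named list: `theta_mean`, `theta_sd`, `phi_mean`, `phi_sd`
#'   (degrees), `n`.
#' @export
angle_summary <- function(field, circular = FALSE) {
  v <- which(field$valid)
  if (length(v) < 2) stop("angle summary needs at least 2 valid voxels")
  th <- field$theta[v]; ph <- field$phi[v]
  if (!circular) {
    list(theta_mean = mean(th), theta_sd = sd(th),
         phi_mean = mean(ph), phi_sd = sd(ph), n = length(v))
  } else {
    axial <- function(a) {
      z <- complex(argument = 2 * a * pi / 180)
      m <- Arg(mean(z)) / 2 * 180 / pi
      if (m < 0) m <- m + 180
      r <- Mod(mean(z))
      list(mean = m, sd = sqrt(-2 * log(max(r, 1e-12))) / 2 * 180 / pi)
    }
    at <- axial(th); ap <- axial(ph)
    list(theta_mean = at$mean, theta_sd = at$sd,
         phi_mean = ap$mean, phi_sd = ap$sd, n = length(v))
  }
}
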