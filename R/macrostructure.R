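#' Local thickness map of a binary structure
#'
#' At every foreground voxel `x`, the local thickness is the diameter of
#' the largest sphere that fits entirely inside the mask and contains `x`
#' (the maximal-inscribed-sphere definition of Hildebrand and
#' Ruegsegger). Computed by distance transform followed by sphere
#' painting from every foreground voxel, which realises the definition
#' exactly on the discrete grid (the grid border counts as background).
#'
#' @param mask a non-empty `mask3d`.
#' @return object of class `thickness_map`: `data` (3D array of
#'   thicknesses in micrometres, 0 off support), `voxel_size`, `summary`
#'   (min, max, mean, sd, count over the support).
#' @export
local_thickness <- function(mask) {
  if (!any(mask$data)) stop("mask is empty")
  d <- dim(mask$data)
  big <- array(FALSE, d + 2L)
  big[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3])] <- mask$data
  r2 <- thickness_paint_cpp(big, dim(big),
                            edt_sq_cpp(big, dim(big)))
  r2 <- array(r2, dim(big))[1L + seq_len(d[1]), 1L + seq_len(d[2]),
                            1L + seq_len(d[3])]
  th <- 2 * sqrt(r2) * mask$voxel_size
  vals <- th[mask$data]
  structure(list(data = th, voxel_size = mask$voxel_size,
                 summary = list(min = min(vals), max = max(vals),
                                mean = mean(vals), sd = sd(vals),
                                count = length(vals))),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<thickness_map> %s voxels; thickness %.4g-%.4g um, mean %.4g +/- %.3g (n = %d)\n",
              paste(dim(x$data), collapse = " x "), s$min, s$max, s$mean,
              s$sd, s$count))
  invisible(x)
}

#' Summarise a thickness map over a region
#'
#' Minimum, maximum, mean, standard deviation and count of the local
#' thickness over the intersection of the map support with `region`,
#' optionally from a seeded random subsample of `n_sub` measurement
#' points (emulating a fixed number of manual measurements).
#'
#' @param tmap a `thickness_map`.
#' @param region optional `mask3d` restricting the summary.
#' @param n_sub optional number of random measurement points.
#' @param seed RNG seed used when subsampling.
#' @return named list: `min`, `max`, `mean`, `sd`, `count`.
#' @export
thickness_summary <- function(tmap, region = NULL, n_sub = NULL, seed = 1L) {
  sel <- tmap$data > 0
  if (!is.null(region)) sel <- sel & region$data
  vals <- tmap$data[sel]
  if (!length(vals)) stop("region does not intersect the thickness support")
  if (!is.null(n_sub) && n_sub < length(vals))
    vals <- with_seed(seed, sample(vals, n_sub))
  list(min = min(vals), max = max(vals), mean = mean(vals),
       sd = if (length(vals) > 1) sd(vals) else 0, count = length(vals))
}

#' Detect spherical bead markers in a volume
#'
#' Beads (e.g. glass fiducials) are assumed brighter than the tissue:
#' voxels above the intensity gate are grouped into 26-connected
#' components, components outside the volume gate are rejected, and each
#' kept component yields an intensity-weighted centre of mass. Labels are
#' assigned by descending component volume, ties broken by lexicographic
#' centroid order.
#'
#' @param volume a `volume3d`.
#' @param intensity_gate threshold intensity, or `"otsu"`.
#' @param volume_gate `c(min, max)` component volume in cubic micrometres.
#' @return object of class `bead_set`: data.frame `beads` with `label`,
#'   `x`, `y`, `z` (micrometres), `volume_um3`; empty (with a warning) if
#'   nothing passes the gates.
#' @export
detect_beads <- function(volume, intensity_gate = "otsu",
                         volume_gate = c(0, Inf)) {
  thr <- if (identical(intensity_gate, "otsu"))
    otsu_threshold(as.vector(volume$data)) else intensity_gate
  m <- volume$data > thr
  vs <- volume$voxel_size
  lab <- array(label_components_cpp(as.vector(m), dim(m), 26L), dim(m))
  labs <- setdiff(unique(as.vector(lab)), 0L)
  rows <- list()
  for (l in labs) {
    idx <- which(lab == l)
    vol_um3 <- length(idx) * vs^3
    if (vol_um3 < volume_gate[1] || vol_um3 > volume_gate[2]) next
    w <- volume$data[idx]
    pos <- index_to_um(idx, dim(m), vs)
    cen <- colSums(pos * w) / sum(w)
    rows[[length(rows) + 1]] <- data.frame(x = cen[1], y = cen[2],
                                           z = cen[3], volume_um3 = vol_um3)
  }
  if (!length(rows)) {
    warning("no bead component passed the gates")
    beads <- data.frame(label = integer(), x = numeric(), y = numeric(),
                        z = numeric(), volume_um3 = numeric())
  } else {
    beads <- do.call(rbind, rows)
    ord <- order(-beads$volume_um3, beads$x, beads$y, beads$z)
    beads <- beads[ord, , drop = FALSE]
    beads <- cbind(label = seq_len(nrow(beads)), beads)
    rownames(beads) <- NULL
  }
  structure(list(beads = beads, threshold = thr), class = "bead_set")
}

#' Tissue elongation from bead-marker pairs
#'
#' For each designated pair of beads, the elongation is the ratio
#' `lambda = l / l0` of their distance in the deformed state to the
#' reference state; the mean over pairs summarises the tissue stretch.
#' Beads are matched across states `by_label` (default; assumes stable
#' labelling) or by `mutual_nearest` centroids after rigid prealignment of
#' the two centroid clouds' barycentres (an error lists unmatched beads).
#' By default all bead pairs are evaluated.
#'
#' @param reference,deformed `bead_set` objects with at least 2 beads.
#' @param pairing `"by_label"` or `"mutual_nearest"`.
#' @param pairs optional 2-column matrix of bead labels designating the
#'   pairs to measure; default all combinations.
#' @return object of class `elongation_result`: data.frame `pairs`
#'   (`label_a`, `label_b`, `l0`, `l`, `lambda`), `lambda_mean`,
#'   `matching` (reference label -> deformed label).
#' @export
elongation <- function(reference, deformed,
                       pairing = c("by_label", "mutual_nearest"),
                       pairs = NULL) {
  pairing <- match.arg(pairing)
  rb <- reference$beads; db <- deformed$beads
  if (nrow(rb) < 2 || nrow(db) < 2)
    stop("elongation needs at least 2 beads per state")
  if (pairing == "by_label") {
    if (nrow(rb) != nrow(db))
      stop("by_label pairing requires equal bead counts")
    match_ref <- rb$label
    match_def <- rb$label
  } else {
    rc <- as.matrix(rb[, c("x", "y", "z")])
    dc <- as.matrix(db[, c("x", "y", "z")])
    rcc <- sweep(rc, 2, colMeans(rc))
    dcc <- sweep(dc, 2, colMeans(dc))
    dmat <- outer(rowSums(rcc^2), rowSums(dcc^2), "+") -
            2 * rcc %*% t(dcc)
    fwd <- apply(dmat, 1, which.min)
    bwd <- apply(dmat, 2, which.min)
    mutual <- bwd[fwd] == seq_len(nrow(rb))
    if (!all(mutual) || anyDuplicated(fwd))
      stop("mutual_nearest pairing is not bijective; unmatched reference beads: ",
           paste(rb$label[!mutual], collapse = ", "))
    match_ref <- rb$label
    match_def <- db$label[fwd]
  }
  ref_pos <- as.matrix(rb[match(match_ref, rb$label), c("x", "y", "z")])
  def_pos <- as.matrix(db[match(match_def, db$label), c("x", "y", "z")])
  n <- length(match_ref)
  if (is.null(pairs)) {
    cmb <- utils::combn(n, 2)
    pairs_idx <- t(cmb)
  } else {
    pairs_idx <- cbind(match(pairs[, 1], match_ref),
                       match(pairs[, 2], match_ref))
  }
  l0 <- sqrt(rowSums((ref_pos[pairs_idx[, 1], , drop = FALSE] -
                      ref_pos[pairs_idx[, 2], , drop = FALSE])^2))
  l1 <- sqrt(rowSums((def_pos[pairs_idx[, 1], , drop = FALSE] -
                      def_pos[pairs_idx[, 2], , drop = FALSE])^2))
  tab <- data.frame(label_a = match_ref[pairs_idx[, 1]],
                    label_b = match_ref[pairs_idx[, 2]],
                    l0 = l0, l = l1, lambda = l1 / l0)
  structure(list(pairs = tab, lambda_mean = mean(tab$lambda),
                 matching = data.frame(reference = match_ref,
                                       deformed = match_def)),
            class = "elongation_result")
}

#' @export
print.elongation_result <- function(x, ...) {
  cat(sprintf("<elongation_result> %d pairs, mean lambda = %.4f\n",
              nrow(x$pairs), x$lambda_mean))
  invisible(x)
}
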