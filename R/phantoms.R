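#' Specification of a wavy fibre network phantom
#'
#' Declares the generative model for a synthetic volume emulating a wavy
#' fibrous network (e.g. muscular fibre bundles): straight mean axes drawn
#' from a Watson axial distribution about a mean direction, with sinusoidal
#' transverse undulation of common period and independent amplitudes along
#' the two transverse axes of each fibre, voxelised as tubes.
#'
#' Defaults mirror a "medium resolution" tomographic acquisition of the
#' vocalis-type network: 13 um voxels, mean fibre direction along the
#' anteroposterior axis e_y, waviness period 1.5 mm with transverse
#' amplitudes (198, 220) um, and a concentration `kappa` calibrated toward
#' the reported polar-angle spread sd(theta) of about 25 degrees (with
#' these waviness amplitudes the generative tangent spread saturates near
#' 29 degrees; see the methods vignette).
#'
#' @param shape integer(3) grid shape, each >= 32.
#' @param voxel_size voxel edge (micrometres).
#' @param mean_direction unit 3-vector, mean fibre axis.
#' @param kappa Watson concentration (>= 0; 0 = isotropic axes).
#' @param radius_mean,radius_sd fibre radius distribution (micrometres).
#' @param n_fibres number of fibres.
#' @param R0 length-2 waviness amplitudes (micrometres) along the two
#'   transverse axes of each fibre.
#' @param lambda waviness spatial period (micrometres).
#' @param random_phase randomise the per-fibre waviness phases?
#' @param random_roll randomise each fibre's transverse-frame roll angle
#'   about its axis? Keeps the network statistically transversely
#'   isotropic (default). Disable to pin the two waviness amplitudes to
#'   reproducible transverse planes (e.g. for plane-resolved waviness
#'   recovery).
#' @param fg,bg foreground/background intensity levels.
#' @param seed RNG seed (generation is bit-reproducible for a fixed seed).
#' @return a list of class `fibre_phantom_spec`.
#' @export
fibre_phantom_spec <- function(shape = c(128L, 128L, 128L),
                               voxel_size = 13,
                               mean_direction = c(0, 1, 0),
                               kappa = 40,
                               radius_mean = 40, radius_sd = 7,
                               n_fibres = 250L,
                               R0 = c(198, 220),
                               lambda = 1500,
                               random_phase = TRUE,
                               random_roll = TRUE,
                               fg = 200, bg = 50,
                               seed = 1L) {
  if (any(shape < 32)) stop("grid shape must be at least 32 voxels per axis")
  if (kappa < 0) stop("kappa must be >= 0")
  if (radius_mean <= 0) stop("fibre radii must be positive")
  if (lambda <= 0) stop("waviness period must be positive")
  if (any(R0 < 0)) stop("waviness amplitudes must be >= 0")
  md <- mean_direction / sqrt(sum(mean_direction^2))
  structure(list(shape = as.integer(shape), voxel_size = voxel_size,
                 mean_direction = md, kappa = kappa,
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 n_fibres = as.integer(n_fibres), R0 = R0, lambda = lambda,
                 random_phase = isTRUE(random_phase),
                 random_roll = isTRUE(random_roll), fg = fg, bg = bg,
                 seed = as.integer(seed)),
            class = "fibre_phantom_spec")
}

# Watson axial distribution, density ~ exp(kappa * (mu . d)^2) on the
# sphere, sampled by rejection from the uniform sphere (axial: d and -d
# are the same direction).
sample_watson <- function(n, mu, kappa) {
  if (is.infinite(kappa))   # perfectly aligned axes
    return(matrix(mu, n, 3, byrow = TRUE))
  out <- matrix(0, n, 3)
  got <- 0L
  while (got < n) {
    m <- max(64L, 2L * (n - got))
    z <- matrix(rnorm(3L * m), m, 3)
    z <- z / sqrt(rowSums(z^2))
    keep <- runif(m) < exp(kappa * ((z %*% mu)^2 - 1))
    z <- z[keep, , drop = FALSE]
    take <- min(nrow(z), n - got)
    if (take > 0) {
      out[got + seq_len(take), ] <- z[seq_len(take), , drop = FALSE]
      got <- got + take
    }
  }
  out
}

# Deterministic orthonormal transverse frame (n1, n2) for an axis d.
transverse_frame <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  n1 <- ref - sum(ref * d) * d
  n1 <- n1 / sqrt(sum(n1^2))
  n2 <- c(d[2] * n1[3] - d[3] * n1[2],
          d[3] * n1[1] - d[1] * n1[3],
          d[1] * n1[2] - d[2] * n1[1])
  list(n1 = n1, n2 = n2)
}

#' Generate a wavy fibre network phantom with ground truth
#'
#' Voxelises a union of tubes around sinusoidal centrelines
#' `x(t) = x0 + t d + R0_1 sin(2 pi t / lambda + psi_1) n1
#'                 + R0_2 sin(2 pi t / lambda + psi_2) n2`
#' where `d` is drawn from a Watson axial distribution about the mean
#' direction and `(n1, n2)` is the transverse frame of `d`. A voxel is
#' foreground iff its centre lies within the fibre radius of the densely
#' sampled centreline (sampling step 0.25 voxel of arc length). The
#' generative orientation tensor `A_gen` is computed by arc-length-weighted
#' averaging of the (dense, step far below 0.1 lambda) unit tangents of all
#' in-grid centreline samples.
#'
#' @param spec a [fibre_phantom_spec()].
#' @return list of class `phantom` with elements `volume` (a `volume3d`)
#'   and `truth` (centrelines, radii, axes, frames, `A_gen`, `lambda`,
#'   `R0`, analytic tube volume, the spec).
#' @export
make_fibre_phantom <- function(spec) {
  stopifnot(inherits(spec, "fibre_phantom_spec"))
  vs <- spec$voxel_size
  ext <- spec$shape * vs
  with_seed(spec$seed, {
    axes_f <- sample_watson(spec$n_fibres, spec$mean_direction, spec$kappa)
    radii <- pmax(0.5 * vs, rnorm(spec$n_fibres, spec$radius_mean,
                                  spec$radius_sd))
    x0 <- cbind(runif(spec$n_fibres, 0, ext[1]),
                runif(spec$n_fibres, 0, ext[2]),
                runif(spec$n_fibres, 0, ext[3]))
    psi <- if (spec$random_phase) {
      matrix(runif(2L * spec$n_fibres, 0, 2 * pi), ncol = 2)
    } else {
      # coherent mode: lock the phase to the absolute position along the
      # fibre axis so that all fibres undulate in step through space
      # (bundle-coherent waviness), not merely with equal phase offsets
      ph0 <- 2 * pi * rowSums(x0 * axes_f) / spec$lambda
      cbind(ph0, ph0)
    }
    roll <- if (spec$random_roll) runif(spec$n_fibres, 0, 2 * pi)
            else rep(0, spec$n_fibres)

    om <- 2 * pi / spec$lambda
    speed_bound <- 1 + om * (spec$R0[1] + spec$R0[2])
    dt <- 0.25 * vs / speed_bound
    Tmax <- sqrt(sum(ext^2))
    tgrid <- seq(-Tmax, Tmax, by = dt)

    A_acc <- matrix(0, 3, 3)
    w_acc <- 0
    tube_len <- numeric(spec$n_fibres)
    centrelines <- vector("list", spec$n_fibres)
    all_pts <- vector("list", spec$n_fibres)
    for (f in seq_len(spec$n_fibres)) {
      d <- axes_f[f, ]
      fr <- transverse_frame(d)
      if (roll[f] != 0) {
        n1 <- cos(roll[f]) * fr$n1 + sin(roll[f]) * fr$n2
        fr$n2 <- -sin(roll[f]) * fr$n1 + cos(roll[f]) * fr$n2
        fr$n1 <- n1
      }
      ph <- om * tgrid
      s1 <- spec$R0[1] * sin(ph + psi[f, 1])
      s2 <- spec$R0[2] * sin(ph + psi[f, 2])
      pts <- outer(tgrid, d) + outer(s1, fr$n1) + outer(s2, fr$n2)
      pts <- sweep(pts, 2, x0[f, ], "+")
      inb <- pts[, 1] >= 0 & pts[, 1] < ext[1] &
             pts[, 2] >= 0 & pts[, 2] < ext[2] &
             pts[, 3] >= 0 & pts[, 3] < ext[3]
      if (!any(inb)) { centrelines[[f]] <- matrix(0, 0, 3); next }
      c1 <- spec$R0[1] * om * cos(ph + psi[f, 1])
      c2 <- spec$R0[2] * om * cos(ph + psi[f, 2])
      tang <- outer(rep(1, length(tgrid)), d) + outer(c1, fr$n1) +
              outer(c2, fr$n2)
      tang <- tang[inb, , drop = FALSE]
      spd <- sqrt(rowSums(tang^2))
      tang <- tang / spd
      w <- spd * dt
      A_acc <- A_acc + crossprod(tang * sqrt(w))
      w_acc <- w_acc + sum(w)
      tube_len[f] <- sum(w)
      pts_in <- pts[inb, , drop = FALSE]
      keep_every <- max(1L, floor(nrow(pts_in) / 400))
      centrelines[[f]] <- pts_in[seq(1, nrow(pts_in), by = keep_every), ,
                                 drop = FALSE]
      all_pts[[f]] <- pts_in
    }
    if (w_acc == 0) stop("phantom spec produced no in-grid centreline")
    A_gen <- A_acc / w_acc

    np <- vapply(all_pts, function(p) if (is.null(p)) 0L else nrow(p),
                 integer(1))
    pts_all <- do.call(rbind, all_pts[np > 0])
    rad_all <- rep(radii[np > 0], np[np > 0])
    fg_mask <- paint_balls_cpp(pts_all / vs, rad_all / vs, spec$shape)
    if (!any(fg_mask))
      stop("phantom spec produced zero foreground voxels")
    vol <- array(spec$bg, spec$shape)
    vol[fg_mask] <- spec$fg

    truth <- list(centrelines = centrelines, radii = radii,
                  axes = axes_f, phases = psi,
                  A_gen = A_gen, lambda_gen = spec$lambda,
                  R0_gen = spec$R0,
                  tube_volume = sum(pi * radii^2 * tube_len),
                  spec = spec)
    structure(list(volume = volume3d(vol, vs), truth = truth),
              class = "phantom")
  })
}

#' Parallel straight-cylinder phantom
#'
#' Non-overlapping circular cylinders of given diameters, all along one
#' axis, laid out along a transverse line through the grid centre.
#'
#' @param diameters cylinder diameters (micrometres); each should be at
#'   least 6 voxels for reliable shape metrics downstream.
#' @param axis unit 3-vector, common cylinder axis.
#' @param spacing centre-to-centre spacing (micrometres); must exceed the
#'   sum of adjacent radii.
#' @param shape,voxel_size,fg,bg grid geometry and intensity levels.
#' @return a `phantom` (volume + ground-truth diameters, axis, centres).
#' @export
make_cylinder_phantom <- function(diameters, axis = c(0, 1, 0), spacing,
                                  shape = c(64L, 64L, 64L), voxel_size = 1,
                                  fg = 200, bg = 50) {
  axis <- axis / sqrt(sum(axis^2))
  nd <- length(diameters)
  if (nd > 1) {
    for (i in seq_len(nd - 1))
      if (spacing <= (diameters[i] + diameters[i + 1]) / 2)
        stop("cylinders overlap: spacing must exceed the sum of radii")
  }
  vs <- voxel_size
  ext <- shape * vs
  fr <- transverse_frame(axis)
  centre <- ext / 2
  offsets <- (seq_len(nd) - (nd + 1) / 2) * spacing
  dt <- 0.25 * vs
  Tmax <- sqrt(sum(ext^2))
  tgrid <- seq(-Tmax, Tmax, by = dt)
  pts_list <- vector("list", nd)
  lines <- vector("list", nd)
  for (i in seq_len(nd)) {
    base <- centre + offsets[i] * fr$n1
    pts <- outer(tgrid, axis) + matrix(base, length(tgrid), 3, byrow = TRUE)
    inb <- pts[, 1] >= 0 & pts[, 1] < ext[1] &
           pts[, 2] >= 0 & pts[, 2] < ext[2] &
           pts[, 3] >= 0 & pts[, 3] < ext[3]
    pts_list[[i]] <- pts[inb, , drop = FALSE]
    lines[[i]] <- pts[inb, , drop = FALSE]
    if (!nrow(pts_list[[i]])) stop("cylinder ", i, " misses the grid")
  }
  np <- vapply(pts_list, nrow, integer(1))
  fg_mask <- paint_balls_cpp(do.call(rbind, pts_list) / vs,
                             rep(diameters / 2, np) / vs, as.integer(shape))
  vol <- array(bg, shape)
  vol[fg_mask] <- fg
  truth <- list(diameters = diameters, axis = axis, centrelines = lines,
                centres = lapply(seq_len(nd),
                                 function(i) centre + offsets[i] * fr$n1))
  structure(list(volume = volume3d(vol, vs), truth = truth),
            class = "phantom")
}

#' Binary slab phantom with prescribed local thickness
#'
#' Builds a slab mask whose thickness along the z grid axis at lateral
#' position (i, j) equals `thickness_field[i, j]` (micrometres, quantised
#' to whole voxels), surrounded by background. Zero-thickness cells are
#' excluded from the mask.
#'
#' @param thickness_field numeric matrix of thicknesses (micrometres);
#'   non-zero entries must be at least 3 voxels.
#' @param voxel_size voxel edge (micrometres).
#' @return a `phantom` with elements `mask` (a `mask3d`) and `truth`
#'   (the voxel-quantised thickness field, micrometres).
#' @export
make_slab_phantom <- function(thickness_field, voxel_size = 1) {
  tv <- round(thickness_field / voxel_size)
  if (any(tv > 0 & tv < 3))
    stop("non-zero thickness must be at least 3 voxels")
  nx <- nrow(tv); ny <- ncol(tv)
  nz <- max(tv) + 4L
  arr <- array(FALSE, c(nx, ny, nz))
  z0 <- 2L  # 0-based offset of the slab base
  for (j in seq_len(ny)) {
    tj <- tv[, j]
    for (i in seq_len(nx))
      if (tj[i] > 0) arr[i, j, (z0 + 1):(z0 + tj[i])] <- TRUE
  }
  truth <- list(thickness = tv * voxel_size, z_base = z0)
  structure(list(mask = mask3d(arr, voxel_size, provenance = "make_slab_phantom"),
                 truth = truth),
            class = "phantom")
}

#' Spherical bead marker phantom
#'
#' Bright spheres on a dark background, emulating glass-bead fiducial
#' markers glued to tissue. Beads must be disjoint and fully inside the
#' grid; a bead clipped by the boundary is an error.
#'
#' @param centroids n x 3 matrix of bead centres (micrometres).
#' @param radius common bead radius (micrometres).
#' @param shape,voxel_size,fg,bg grid geometry and intensity levels.
#' @return a `phantom` (volume + ground-truth centroids and radius).
#' @export
make_bead_phantom <- function(centroids, radius, shape = c(64L, 64L, 64L),
                              voxel_size = 1, fg = 255, bg = 20) {
  centroids <- as.matrix(centroids)
  vs <- voxel_size
  hi <- (shape - 1) * vs
  if (any(centroids - radius < 0) ||
      any(sweep(centroids + radius, 2, hi) > 0))
    stop("bead clipped by the grid boundary")
  n <- nrow(centroids)
  if (n > 1) {
    dd <- as.matrix(dist(centroids))
    diag(dd) <- Inf
    if (any(dd <= 2 * radius)) stop("beads overlap")
  }
  fg_mask <- paint_balls_cpp(centroids / vs, rep(radius / vs, n),
                             as.integer(shape))
  vol <- array(bg, shape)
  vol[fg_mask] <- fg
  truth <- list(centroids = centroids, radius = radius, fg = fg, bg = bg,
                shape = as.integer(shape))
  structure(list(volume = volume3d(vol, vs), truth = truth),
            class = "phantom")
}

#' Apply an affine stretch to a bead phantom
#'
#' Transforms the ground-truth centroids by `stretch` (a 3 x 3 matrix) and
#' re-voxelises the beads; centroids transform exactly. Beads leaving the
#' grid after the transform are an error.
#'
#' @param phantom a bead `phantom` from [make_bead_phantom()].
#' @param stretch 3 x 3 matrix applied to physical coordinates.
#' @return a transformed bead `phantom`.
#' @export
apply_affine <- function(phantom, stretch) {
  tr <- phantom$truth
  if (is.null(tr$centroids)) stop("apply_affine expects a bead phantom")
  newc <- tr$centroids %*% t(stretch)
  make_bead_phantom(newc, tr$radius, tr$shape, phantom$volume$voxel_size,
                    fg = tr$fg, bg = tr$bg)
}

#' Add imaging degradations to a volume
#'
#' Mimics the appearance of propagation phase-contrast reconstructions:
#' Gaussian point-spread blur, a signed edge halo (difference-of-Gaussians
#' overshoot at foreground/background boundaries), and additive Gaussian
#' noise. With all parameters zero the volume is returned unchanged.
#' Deterministic under a fixed seed.
#'
#' @param volume a `volume3d`.
#' @param blur_sigma PSF standard deviation (voxels).
#' @param noise_sd additive Gaussian noise standard deviation (intensity).
#' @param halo_strength multiplier of the signed edge ring (0 = none).
#' @param seed RNG seed for the noise draw.
#' @return a degraded `volume3d`.
#' @export
add_imaging_noise <- function(volume, blur_sigma = 0, noise_sd = 0,
                              halo_strength = 0, seed = 1L) {
  if (blur_sigma < 0 || noise_sd < 0 || halo_strength < 0)
    stop("degradation parameters must be non-negative")
  v <- volume$data
  if (blur_sigma > 0) v <- smooth_gauss(v, blur_sigma)
  if (halo_strength > 0)
    v <- v + halo_strength * (smooth_gauss(volume$data, 1) -
                              smooth_gauss(volume$data, 2))
  if (noise_sd > 0)
    v <- v + with_seed(seed, array(rnorm(length(v), 0, noise_sd), dim(v)))
  volume3d(v, volume$voxel_size, volume$axes)
}
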