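#' Eigenframe of an orientation tensor
#'
#' Orthonormal triad (`e_u`, `e_v`, `e_w`) of eigenvectors of `A`, ordered
#' by descending eigenvalue: `e_u` is the main fibre direction, `e_v` and
#' `e_w` span the transverse planes in which waviness is measured. Signs of
#' `e_u` and `e_v` are fixed so their largest-magnitude component is
#' positive; `e_w = e_u x e_v` so the triad is right-handed. A relative
#' eigenvalue gap below 1e-6 sets the `degenerate` flag (the frame is then
#' arbitrary within the degenerate subspace) instead of erroring.
#'
#' @param A an `orientation_tensor` or symmetric 3 x 3 matrix.
#' @return list of class `eigenframe`: `e_u`, `e_v`, `e_w` (unit vectors),
#'   `values` (descending), `degenerate`.
#' @export
eigenframe <- function(A) {
  M <- if (inherits(A, "orientation_tensor")) A$A else as.matrix(A)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- eg$values
  fixsign <- function(v) if (v[which.max(abs(v))] < 0) -v else v
  e_u <- fixsign(eg$vectors[, 1])
  e_v <- fixsign(eg$vectors[, 2])
  e_w <- c(e_u[2] * e_v[3] - e_u[3] * e_v[2],
           e_u[3] * e_v[1] - e_u[1] * e_v[3],
           e_u[1] * e_v[2] - e_u[2] * e_v[1])
  gap <- min(abs(diff(vals))) / max(abs(vals[1]), 1e-300)
  structure(list(e_u = e_u, e_v = e_v, e_w = e_w, values = vals,
                 degenerate = gap < 1e-6),
            class = "eigenframe")
}

#' Transverse displacement profile of a fibre track
#'
#' Expresses a fibre trajectory (ordered centroid polyline, physical
#' micrometre coordinates) in the orientation eigenframe and returns its
#' transverse displacement along `e_v` (plane `"uv"`) or `e_w` (plane
#' `"uw"`) as a function of position along `e_u`, after removing the
#' best-fit straight line (so a residual mean drift never masquerades as
#' waviness).
#'
#' @param track n x 3 matrix of points (micrometres), n >= 8.
#' @param frame an [eigenframe()].
#' @param plane `"uv"` or `"uw"`.
#' @return data.frame with columns `u` and `v` (micrometres), sorted by
#'   `u`.
#' @export
transverse_profile <- function(track, frame, plane = c("uv", "uw")) {
  plane <- match.arg(plane)
  track <- as.matrix(track)
  if (nrow(track) < 8) stop("track too short for a waviness profile")
  u <- as.vector(track %*% frame$e_u)
  tv <- if (plane == "uv") frame$e_v else frame$e_w
  v <- as.vector(track %*% tv)
  o <- order(u)
  u <- u[o]; v <- v[o]
  v <- v - (coef(lm(v ~ u))[1] + coef(lm(v ~ u))[2] * u)
  data.frame(u = u, v = as.vector(v))
}

# Dominant-period initial guess from the discrete spectrum of v(u)
# resampled on a regular grid.
spectral_period <- function(u, v) {
  n <- length(u)
  span <- max(u) - min(u)
  ug <- seq(min(u), max(u), length.out = n)
  vg <- approx(u, v, xout = ug, rule = 2)$y
  vg <- vg - mean(vg)
  amp <- Mod(fft(vg))[2:floor(n / 2)]
  k <- which.max(amp)
  span / k
}

#' Estimate waviness period and amplitude from a transverse profile
#'
#' Two estimators of the quasi-sinusoidal waviness
#' `v(u) ~ R0 sin(2 pi u / lambda + psi)`:
#' \describe{
#'   \item{extrema}{(automating the classical click-the-peaks procedure)
#'     lightly smooth `v`, locate alternating maxima/minima; the period is
#'     twice the mean consecutive-extremum spacing (sd over spacings) and
#'     the amplitude is the mean absolute extremum displacement (sd over
#'     extrema), read from the raw signal with parabolic sub-sample
#'     refinement. The smoothing window is one fifth of the spectral-peak
#'     period.}
#'   \item{sinefit}{least-squares fit of the sinusoid, the period seeded
#'     from the dominant spectral component and refined by 1D
#'     minimisation; exact (to numerical tolerance) on a pure sinusoid.}
#' }
#'
#' @param signal data.frame with columns `u`, `v` from
#'   [transverse_profile()] (or any sampled signal, micrometres).
#' @param method `"extrema"` or `"sinefit"`.
#' @return list of class `waviness_estimate`: `lambda_mean`, `lambda_sd`,
#'   `R0_mean`, `R0_sd` (micrometres), `n` (number of extremum
#'   measurements, or fitted samples for sinefit), `method`, plus the raw
#'   per-measurement vectors `lambda_samples` and `R0_samples` (extrema
#'   mode) used for pooling.
#' @export
estimate_waviness <- function(signal, method = c("extrema", "sinefit")) {
  method <- match.arg(method)
  u <- signal$u; v <- signal$v
  lam0 <- spectral_period(u, v)
  if (method == "extrema") {
    n <- length(u)
    span <- max(u) - min(u)
    win <- max(1L, round(n * (lam0 / 5) / span))
    if (win %% 2 == 0) win <- win + 1L
    vs <- as.vector(stats::filter(v, rep(1 / win, win), sides = 2))
    core <- which(!is.na(vs))
    ds <- diff(vs[core])
    sgn <- sign(ds)
    sgn[sgn == 0] <- 1
    turns <- which(diff(sgn) != 0) + 1L
    ext_idx <- core[turns]
    # prune low-prominence wiggles: repeatedly drop the adjacent
    # extremum pair with the smallest value difference, until every
    # peak-to-valley swing is a substantial fraction of the amplitude
    amp <- (max(vs[core]) - min(vs[core])) / 2
    while (length(ext_idx) > 2) {
      dv <- abs(diff(vs[ext_idx]))
      j <- which.min(dv)
      if (dv[j] >= 0.4 * amp) break
      ext_idx <- ext_idx[-c(j, j + 1)]
    }
    if (length(ext_idx) < 3)
      stop(sprintf("only %d extrema found, need at least 3",
                   length(ext_idx)))
    refine <- function(i) {   # parabolic sub-sample refinement on raw v
      if (i <= 1 || i >= length(u)) return(c(u[i], v[i]))
      y <- v[(i - 1):(i + 1)]
      denom <- y[1] - 2 * y[2] + y[3]
      if (abs(denom) < 1e-300) return(c(u[i], v[i]))
      d <- 0.5 * (y[1] - y[3]) / denom
      d <- max(-1, min(1, d))
      du <- (u[i + 1] - u[i - 1]) / 2
      c(u[i] + d * du, y[2] - 0.25 * (y[1] - y[3]) * d)
    }
    ref <- t(vapply(ext_idx, refine, numeric(2)))
    spacings <- diff(ref[, 1])
    lam_samples <- 2 * spacings
    r0_samples <- abs(ref[, 2])
    structure(list(lambda_mean = mean(lam_samples),
                   lambda_sd = if (length(lam_samples) > 1) sd(lam_samples) else NA_real_,
                   R0_mean = mean(r0_samples),
                   R0_sd = if (length(r0_samples) > 1) sd(r0_samples) else NA_real_,
                   n = length(ext_idx), method = "extrema",
                   lambda_samples = lam_samples, R0_samples = r0_samples),
              class = "waviness_estimate")
  } else {
    if ((max(u) - min(u)) < 2 * lam0)
      stop("sinefit needs at least 2 periods of samples")
    rss <- function(lam) {
      X <- cbind(sin(2 * pi * u / lam), cos(2 * pi * u / lam))
      sum(lm.fit(X, v)$residuals^2)
    }
    opt <- optimize(rss, interval = c(0.5 * lam0, 2 * lam0),
                    tol = 1e-10 * lam0)
    lam <- opt$minimum
    X <- cbind(sin(2 * pi * u / lam), cos(2 * pi * u / lam))
    ab <- lm.fit(X, v)$coefficients
    r0 <- sqrt(sum(ab^2))
    structure(list(lambda_mean = lam, lambda_sd = NA_real_,
                   R0_mean = r0, R0_sd = NA_real_,
                   n = length(u), method = "sinefit",
                   lambda_samples = lam, R0_samples = r0),
              class = "waviness_estimate")
  }
}

#' @export
print.waviness_estimate <- function(x, ...) {
  cat(sprintf("<waviness_estimate> [%s] lambda = %.4g +/- %.3g um, R0 = %.4g +/- %.3g um (n = %d)\n",
              x$method, x$lambda_mean, x$lambda_sd, x$R0_mean, x$R0_sd, x$n))
  invisible(x)
}

#' Waviness from the oscillation of the local fibre angle
#'
#' Alternative estimator that needs no single-fibre tracks: within a
#' dense orientation field, the local in-plane fibre angle oscillates
#' quasi-sinusoidally along the main direction `e_u` when the network is
#' wavy. The mean in-plane angle of the valid voxels is binned along
#' `e_u`, the period `lambda` of that angle signal is estimated as usual,
#' and the angular amplitude `Phi` (the peak slope of the centreline)
#' is converted to a displacement amplitude via
#' `R0 = lambda * tan(Phi) / (2 pi)`. The conversion assumes a clean
#' sinusoid and is documented as approximate.
#'
#' @param field an `orientation_field`.
#' @param frame an [eigenframe()].
#' @param plane `"uv"` or `"uw"`.
#' @param bin_width_um bin width along `e_u` (default one voxel).
#' @param method passed to [estimate_waviness()] for the angle signal.
#' @return a `waviness_estimate` (method tag `"phi_profile"`).
#' @export
waviness_from_phi <- function(field, frame, plane = c("uv", "uw"),
                              bin_width_um = NULL,
                              method = c("extrema", "sinefit")) {
  plane <- match.arg(plane)
  method <- match.arg(method)
  vs <- field$voxel_size
  if (is.null(bin_width_um)) bin_width_um <- vs
  v <- which(field$valid)
  if (length(v) < 10) stop("too few valid voxels for a phi profile")
  pos <- index_to_um(v, dim(field$valid), vs)
  u <- as.vector(pos %*% frame$e_u)
  tv <- if (plane == "uv") frame$e_v else frame$e_w
  p <- cbind(field$px[v], field$py[v], field$pz[v])
  # in-plane angle of p within (e_u, transverse) plane, in radians
  ang <- atan2(p %*% tv, p %*% frame$e_u)
  ang[ang > pi / 2] <- ang[ang > pi / 2] - pi    # axial wrap
  ang[ang < -pi / 2] <- ang[ang < -pi / 2] + pi
  bins <- floor((u - min(u)) / bin_width_um)
  ub <- tapply(u, bins, mean)
  ab <- tapply(as.vector(ang), bins, mean)
  sig <- data.frame(u = as.vector(ub), v = as.vector(ab))
  sig <- sig[order(sig$u), ]
  sig$v <- sig$v - mean(sig$v)
  est <- estimate_waviness(sig, method)
  phi_amp <- est$R0_mean   # radians (amplitude of the angle signal)
  r0 <- est$lambda_mean * tan(phi_amp) / (2 * pi)
  structure(list(lambda_mean = est$lambda_mean, lambda_sd = est$lambda_sd,
                 R0_mean = r0, R0_sd = NA_real_, n = est$n,
                 method = "phi_profile",
                 lambda_samples = est$lambda_samples, R0_samples = r0),
            class = "waviness_estimate")
}

#' Waviness report over both transverse eigenplanes
#'
#' Aggregates waviness over a set of fibre tracks: for each of the `uv`
#' and `uw` planes, per-track transverse profiles are estimated and the
#' per-measurement samples pooled (mean +/- sd over the pooled
#' measurements). A warning is emitted when a plane accumulates fewer
#' than 50 measurements, the customary floor for reporting these
#' descriptors. Tracks too short to analyse are skipped (with a warning);
#' at least one usable track is required.
#'
#' @param tracks list of n x 3 matrices (physical micrometre coordinates).
#' @param frame an [eigenframe()].
#' @param method passed to [estimate_waviness()].
#' @return list with elements `uv` and `uw`, each a `waviness_estimate`.
#' @export
waviness_report <- function(tracks, frame, method = c("extrema", "sinefit")) {
  method <- match.arg(method)
  one_plane <- function(plane) {
    lam <- c(); r0 <- c(); n_tot <- 0L; used <- 0L
    for (tr in tracks) {
      est <- tryCatch({
        prof <- transverse_profile(tr, frame, plane)
        estimate_waviness(prof, method)
      }, error = function(e) NULL)
      if (is.null(est)) next
      lam <- c(lam, est$lambda_samples)
      r0 <- c(r0, est$R0_samples)
      n_tot <- n_tot + est$n
      used <- used + 1L
    }
    if (used == 0L) stop("no usable track for plane ", plane)
    if (n_tot < 50)
      warning(sprintf("plane %s: only %d waviness measurements (< 50)",
                      plane, n_tot))
    structure(list(lambda_mean = mean(lam),
                   lambda_sd = if (length(lam) > 1) sd(lam) else NA_real_,
                   R0_mean = mean(r0),
                   R0_sd = if (length(r0) > 1) sd(r0) else NA_real_,
                   n = n_tot, method = method, tracks_used = used,
                   lambda_samples = lam, R0_samples = r0),
              class = "waviness_estimate")
  }
  list(uv = one_plane("uv"), uw = one_plane("uw"))
}
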