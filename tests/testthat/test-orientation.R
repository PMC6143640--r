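test_that("grey gradient matches analytic derivatives", {
  d <- c(24, 8, 8)
  # linear ramp along x: constant interior gradient a = 3 / voxel_size
  ramp <- array(rep(3 * (0:23), 64), d)
  g <- grey_gradient(volume3d(ramp, 2))
  expect_equal(g$gx[2:23, 4, 4], rep(1.5, 22), tolerance = 1e-12)
  expect_equal(max(abs(g$gy)), 0)
  expect_equal(max(abs(g$gz)), 0)
  # constant volume: zero field
  g0 <- grey_gradient(volume3d(array(7, c(5, 5, 5)), 1))
  expect_equal(max(abs(g0$gx), abs(g0$gy), abs(g0$gz)), 0)
  # sinusoid: max slope within discretisation error of the analytic 2*pi/L
  L <- 32
  sine <- array(rep(sin(2 * pi * (0:63) / L), 16), c(64, 4, 4))
  gs <- grey_gradient(volume3d(sine, 1))
  expect_equal(max(abs(gs$gx[, 2, 2])), 2 * pi / L,
               tolerance = (2 * pi / L)^2)
})

test_that("structure tensors are PSD and track elongated textures", {
  ph <- make_cylinder_phantom(16, axis = c(0, 1, 0), spacing = 1,
                              shape = c(40, 40, 40), voxel_size = 1)
  st <- structure_tensor_field(grey_gradient(ph$volume), 9)
  # symmetric PSD at a probe voxel
  i <- c(20, 20, 20)
  S <- matrix(c(st$sxx[i[1], i[2], i[3]], st$sxy[i[1], i[2], i[3]],
                st$sxz[i[1], i[2], i[3]], st$sxy[i[1], i[2], i[3]],
                st$syy[i[1], i[2], i[3]], st$syz[i[1], i[2], i[3]],
                st$sxz[i[1], i[2], i[3]], st$syz[i[1], i[2], i[3]],
                st$szz[i[1], i[2], i[3]]), 3, 3)
  expect_true(all(eigen(S, symmetric = TRUE)$values > -1e-12))
  # minor eigenvector along the cylinder axis
  f <- recover_A(ph$volume, 9)
  p <- fibrequant:::valid_vectors(f)
  ang <- acos(pmin(1, abs(p[, 2]))) * 180 / pi
  expect_gt(mean(ang < 3), 0.95)
  # zero gradient -> zero tensor
  st0 <- structure_tensor_field(grey_gradient(volume3d(array(1, c(9, 9, 9)), 1)), 3)
  expect_equal(max(abs(st0$sxx)), 0)
  expect_error(structure_tensor_field(grey_gradient(volume3d(array(1, c(9, 9, 9)), 1)), 4),
               "odd")
  # isotropic noise: eigenvalue ratio mu3/mu1 approaches 1 in expectation
  rat <- vapply(1:3, function(s) {
    set.seed(s)
    nv <- volume3d(array(rnorm(20^3), c(20, 20, 20)), 1)
    stn <- structure_tensor_field(grey_gradient(nv), 9)
    idx <- which(array(TRUE, c(20, 20, 20)))
    S6 <- cbind(stn$sxx[idx], stn$syy[idx], stn$szz[idx],
                stn$sxy[idx], stn$sxz[idx], stn$syz[idx])
    mu <- fibrequant:::minor_eigs_cpp(S6)$mu
    mean(mu[, 3] / mu[, 1])
  }, numeric(1))
  expect_gt(mean(rat), 0.6)   # far from the ~0 of an oriented texture
})

test_that("angle extraction is canonical and invertible", {
  a <- angles_from_vector(c(0, 1, 0))
  expect_equal(c(a$theta, a$phi), c(90, 90))
  expect_equal(angles_from_vector(c(1, 0, 0)),
               angles_from_vector(c(-1, 0, 0)))
  expect_equal(unlist(angles_from_vector(c(1, 0, 0))),
               c(theta = 90, phi = 0))
  expect_equal(unlist(angles_from_vector(c(0, 0, 1))),
               c(theta = 0, phi = 0))
  expect_error(angles_from_vector(c(0, 0, 0)), "zero vector")
  # reconstruction through the spherical parameterisation
  set.seed(5)
  p <- matrix(rnorm(300), 100, 3)
  p <- p / sqrt(rowSums(p^2))
  ang <- angles_from_vector(p)
  th <- ang$theta * pi / 180; phi <- ang$phi * pi / 180
  rec <- cbind(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))
  pc <- fibrequant:::canonicalize_axial(p)
  expect_equal(rec, pc, tolerance = 1e-9)
  expect_true(all(ang$theta >= 0 & ang$theta <= 180))
  expect_true(all(ang$phi >= 0 & ang$phi < 180))
})

test_that("orientation field validity gates work", {
  ph <- make_cylinder_phantom(16, axis = c(0, 1, 0), spacing = 1,
                              shape = c(40, 40, 40), voxel_size = 1)
  m <- threshold_volume(ph$volume, "otsu")
  dm <- euclidean_distance_map(m)
  st <- structure_tensor_field(grey_gradient(ph$volume), 9)
  f <- orientation_field(st, m, dm, min_coherence = 0.2)
  expect_true(all(f$valid[which(f$valid)]))
  expect_true(all(!f$valid | m$data))       # valid implies inside mask
  # impossible coherence -> empty field
  f0 <- orientation_field(st, m, dm, min_coherence = 1.01)
  expect_equal(sum(f0$valid), 0)
  # flipping the volume along e_x maps phi -> 180 - phi
  ph2 <- make_fibre_phantom(fibre_phantom_spec(
    shape = c(48, 48, 48), n_fibres = 30L, radius_mean = 30,
    lambda = 600, R0 = c(60, 60), kappa = 5, seed = 2,
    mean_direction = c(1, 1, 0) / sqrt(2)))
  ff <- recover_A(ph2$volume, 9)
  flip <- volume3d(ph2$volume$data[dim(ph2$volume$data)[1]:1, , ],
                   ph2$volume$voxel_size)
  fl <- recover_A(flip, 9)
  n1 <- dim(ff$valid)[1]
  vboth <- ff$valid & fl$valid[n1:1, , ]
  ph_f <- ff$phi[which(vboth)]
  ph_l <- fl$phi[n1:1, , ][which(vboth)]
  dphi <- abs((180 - ph_f) %% 180 - ph_l)
  dphi <- pmin(dphi, 180 - dphi)
  expect_lt(median(dphi), 1.5)
})

test_that("orientation tensors match direct summation and stay consistent", {
  expect_equal(orientation_tensor(rbind(c(0, 1, 0), c(0, -1, 0)))$A,
               diag(c(0, 1, 0)), tolerance = 1e-15)
  expect_equal(orientation_tensor(diag(3))$A, diag(3) / 3,
               tolerance = 1e-15)
  set.seed(11)
  p <- fibrequant:::sample_watson(10000, c(0, 1, 0), 5)
  A <- orientation_tensor(p)$A
  # brute-force summation oracle
  Ao <- matrix(0, 3, 3)
  for (i in 1:10000) Ao <- Ao + p[i, ] %o% p[i, ]
  Ao <- Ao / 10000
  expect_lt(max(abs(A - Ao)), 1e-12)
  expect_lt(abs(A[1, 1] - A[3, 3]), 0.02)
  expect_equal(sum(diag(A)), 1, tolerance = 1e-9)
  expect_error(orientation_tensor(matrix(0, 0, 3)), "no valid")
})

test_that("planar orientation tensor projects and renormalises", {
  expect_equal(orientation_tensor_2d(rbind(c(0, 1, 0)), c("x", "y"))$A,
               matrix(c(0, 0, 0, 1), 2, 2), tolerance = 1e-15)
  set.seed(13)
  ang <- runif(5000, 0, pi)
  p <- cbind(cos(ang), sin(ang), 0)
  A2 <- orientation_tensor_2d(p, c("x", "y"))$A
  expect_lt(max(abs(A2 - diag(2) / 2)), 0.03)   # Monte-Carlo isotropy
  set.seed(14)
  q <- matrix(rnorm(300), 100, 3); q <- q / sqrt(rowSums(q^2))
  expect_equal(sum(diag(orientation_tensor_2d(q, c("x", "z"))$A)), 1,
               tolerance = 1e-12)
  expect_error(orientation_tensor_2d(rbind(c(0, 0, 1)), c("x", "y")),
               "degenerate")
})

test_that("ODF histogram and peak finding behave per contract", {
  d <- c(6, 6, 6)
  f <- structure(list(px = array(0, d), py = array(0, d), pz = array(0, d),
                      theta = array(90, d), phi = array(90, d),
                      coherence = array(1, d), valid = array(TRUE, d),
                      w = 9L, voxel_size = 1),
                 class = "orientation_field")
  h <- odf_histogram(f, 3)
  expect_equal(sum(h$freq), 1, tolerance = 1e-12)
  pk <- find_odf_peaks(h)
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$theta, pk$phi), c(91.5, 91.5))
  # two equal clusters 60 degrees apart -> exactly 2 peaks
  set.seed(21)
  n <- 2000
  th <- c(rnorm(n, 60, 4), rnorm(n, 120, 4))
  phv <- rnorm(2 * n, 90, 4)
  d2 <- c(2 * n, 1, 1)
  f2 <- structure(list(theta = array(pmin(179, pmax(0, th)), d2),
                       phi = array(pmin(179, pmax(0, phv)), d2),
                       coherence = array(1, d2), valid = array(TRUE, d2),
                       px = array(0, d2), py = array(0, d2),
                       pz = array(0, d2), w = 9L, voxel_size = 1),
                  class = "orientation_field")
  pk2 <- find_odf_peaks(odf_histogram(f2, 3))
  expect_equal(nrow(pk2), 2)
  expect_equal(sort(pk2$theta), c(60, 120), tolerance = 5)
})

test_that("angle summaries match analytic moments", {
  d <- c(5, 5, 4)
  f <- structure(list(theta = array(82, d), phi = array(82, d),
                      coherence = array(1, d), valid = array(TRUE, d),
                      px = array(0, d), py = array(0, d), pz = array(0, d),
                      w = 9L, voxel_size = 1),
                 class = "orientation_field")
  s <- angle_summary(f)
  expect_equal(c(s$theta_mean, s$phi_mean), c(82, 82))
  expect_equal(c(s$theta_sd, s$phi_sd), c(0, 0))
  # uniform theta on [80, 100]: mean 90, sd 20/sqrt(12)
  m <- 20000
  f2 <- structure(list(theta = array(seq(80, 100, length.out = m), c(m, 1, 1)),
                       phi = array(90, c(m, 1, 1)),
                       coherence = array(1, c(m, 1, 1)),
                       valid = array(TRUE, c(m, 1, 1)),
                       px = array(0, c(m, 1, 1)), py = array(0, c(m, 1, 1)),
                       pz = array(0, c(m, 1, 1)), w = 9L, voxel_size = 1),
                  class = "orientation_field")
  s2 <- angle_summary(f2)
  expect_equal(s2$theta_mean, 90, tolerance = 1e-9)
  expect_equal(s2$theta_sd, 20 / sqrt(12), tolerance = 1e-3)
})

test_that("A is antipodal-invariant and rotation-equivariant", {
  set.seed(31)
  p <- fibrequant:::sample_watson(500, c(0.3, 0.9, 0.3) / sqrt(0.99), 4)
  expect_equal(orientation_tensor(p)$A, orientation_tensor(-p)$A,
               tolerance = 1e-15)
  # rotating a phantom by 90 degrees transforms A as R A R^T
  ph <- make_fibre_phantom(fibre_phantom_spec(
    shape = c(48, 48, 48), n_fibres = 40L, radius_mean = 30,
    lambda = 500, R0 = c(40, 40), kappa = 10, seed = 6,
    mean_direction = c(0.2, 1, 0.1) / sqrt(1.05)))
  A0 <- orientation_tensor(recover_A(ph$volume, 9))$A
  for (rot in list(list(f = rot90_z, R = R_z), list(f = rot90_x, R = R_x))) {
    vr <- volume3d(rot$f(ph$volume$data), ph$volume$voxel_size)
    Ar <- orientation_tensor(recover_A(vr, 9))$A
    expect_lt(max(abs(Ar - rot$R %*% A0 %*% t(rot$R))), 0.03)
  }
})

test_that("eigen-decomposition agrees with characteristic-polynomial roots", {
  set.seed(41)
  for (i in 1:10) {
    M <- crossprod(matrix(rnorm(9), 3, 3))
    M <- M / sum(diag(M))
    ev <- sort(eigen(M, symmetric = TRUE)$values)
    # roots of det(M - x I) via polyroot
    cpoly <- c(-det(M),
               M[1, 1] * M[2, 2] - M[1, 2]^2 +
               M[1, 1] * M[3, 3] - M[1, 3]^2 +
               M[2, 2] * M[3, 3] - M[2, 3]^2,
               -sum(diag(M)), 1)
    roots <- sort(Re(polyroot(cpoly)))
    expect_equal(ev, roots, tolerance = 1e-8)
  }
})
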