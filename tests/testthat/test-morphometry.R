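test_that("axis-aligned resampling returns raw planes exactly", {
  ph <- make_cylinder_phantom(12, axis = c(0, 1, 0), spacing = 1,
                              shape = c(32, 32, 32), voxel_size = 1)
  m <- threshold_volume(ph$volume, "fixed", value = 100)
  stk <- resample_perpendicular(m, c(0, 1, 0))
  expect_equal(length(stk$slices), 32)
  expect_identical(stk$slices[[10]], m$data[, 10, ])
})

test_that("oblique resampling preserves sections and total volume", {
  dir <- c(0.3, 1, 0.25); dir <- dir / sqrt(sum(dir^2))
  ph <- make_cylinder_phantom(20, axis = dir, spacing = 1,
                              shape = c(56, 56, 56), voxel_size = 1)
  m <- threshold_volume(ph$volume, "fixed", value = 100)
  stk <- resample_perpendicular(m, dir)
  secs <- sections_from_stack(stk)
  mid <- secs[secs$slice > 20 & secs$slice < max(secs$slice) - 20, ]
  expect_gt(nrow(mid), 5)
  expect_lt(abs(median(mid$d_e) - 20) / 20, 0.05)
  expect_gt(median(mid$xi), 0.9)
  vol_in <- sum(m$data)
  vol_out <- sum(vapply(stk$slices, sum, numeric(1)))
  expect_lt(abs(vol_out - vol_in) / vol_in, 0.05)
})

test_that("section morphometry matches analytic shapes", {
  # digital disc r = 10: d_e within 3%, xi >= 0.95, P within 3% of pi*d
  df <- detect_sections(disc_slice(10), 1)
  expect_equal(nrow(df), 1)
  expect_lt(abs(df$d_e - 20) / 20, 0.03)
  expect_gt(df$xi, 0.95)
  expect_lte(df$xi, 1.05)
  expect_lt(abs(df$perimeter - 20 * pi) / (20 * pi), 0.03)
  # perimeter error < 3% for d >= 15 px; xi approaches 1 monotonically
  xis <- vapply(c(5, 10, 20, 40), function(r)
    detect_sections(disc_slice(r), 1)$xi, numeric(1))
  for (r in c(10, 20, 40)) {
    dfr <- detect_sections(disc_slice(r), 1)
    expect_lt(abs(dfr$perimeter - 2 * pi * r) / (2 * pi * r), 0.03)
  }
  expect_true(all(abs(diff(abs(xis - 1))) < 0.06))  # no wild swings
  expect_lt(abs(xis[4] - 1), abs(xis[1] - 1) + 0.01)
  # square: xi -> pi/4 as side grows
  dfs <- detect_sections(square_slice(48), 1)
  expect_lt(abs(dfs$xi - pi / 4), 0.05)
  # two disjoint discs with correct centroids
  d1 <- disc_slice(6, 25); d2 <- disc_slice(6, 25)
  two <- rbind(cbind(d1, matrix(FALSE, 25, 5)),
               cbind(matrix(FALSE, 25, 5), d2))
  dft <- detect_sections(two, 2)
  expect_equal(nrow(dft), 2)
  expect_equal(sort(dft$cu), sort(c(12, 37)) * 2, tolerance = 2)
  # empty slice is fine
  expect_equal(nrow(detect_sections(matrix(FALSE, 10, 10), 1)), 0)
})

test_that("d_e is invariant under slice rotations and order reversal", {
  sl <- disc_slice(8)
  a <- detect_sections(sl, 1)
  b <- detect_sections(t(sl)[, rev(seq_len(nrow(sl)))], 1)  # 90 deg rot
  expect_equal(a$d_e, b$d_e, tolerance = 1e-9)
  expect_equal(a$xi, b$xi, tolerance = 1e-9)
})

test_that("track linking and the misalignment filter behave per contract", {
  ph <- make_cylinder_phantom(c(10, 10, 10), axis = c(0, 1, 0),
                              spacing = 16, shape = c(64, 64, 64),
                              voxel_size = 1)
  m <- threshold_volume(ph$volume, "fixed", value = 100)
  stk <- resample_perpendicular(m, c(0, 1, 0))
  secs <- sections_from_stack(stk)
  trk <- link_tracks(secs, max_jump = 2)
  expect_equal(length(trk), 3)   # one track per cylinder
  flt <- misalignment_filter(trk, c(0, 1, 0), 30)
  expect_equal(length(flt$kept), 3)
  expect_equal(length(flt$discarded), 0)
  # max_jump = 0: all singletons
  t0 <- link_tracks(secs, max_jump = 0)
  expect_equal(length(t0), nrow(secs))
  # cylinder tilted 45 degrees from the main direction is discarded
  ph45 <- make_cylinder_phantom(10, axis = c(0, 1, 1) / sqrt(2),
                                spacing = 1, shape = c(64, 64, 64),
                                voxel_size = 1)
  m45 <- threshold_volume(ph45$volume, "fixed", value = 100)
  st45 <- resample_perpendicular(m45, c(0, 1, 0))
  tr45 <- link_tracks(sections_from_stack(st45), max_jump = 3)
  tr45 <- tr45[vapply(tr45, function(t) nrow(t$centroids), integer(1)) > 5]
  f45 <- misalignment_filter(tr45, c(0, 1, 0), 30)
  expect_gt(length(f45$discarded), 0)
  expect_equal(length(f45$kept), 0)
})

test_that("density and distribution summaries are exact on constructions", {
  ph <- make_cylinder_phantom(rep(10, 10), axis = c(0, 1, 0), spacing = 12,
                              shape = c(140, 24, 40), voxel_size = 1)
  m <- threshold_volume(ph$volume, "fixed", value = 100)
  stk <- resample_perpendicular(m, c(0, 1, 0))
  secs <- sections_from_stack(stk)
  expect_true(all(table(secs$slice) == 10))
  st <- density_and_stats(secs, slice_area_mm2 = 0.1)
  expect_equal(st$density_mm2, 100)
  # all-equal discs: peak = median = d_e of the disc
  expect_equal(st$d_e_peak, st$d_e_median, tolerance = 0.5)
  expect_equal(st$d_e_median, 10, tolerance = 0.5)
  # mixture of two diameters: mode equals the majority diameter
  ph2 <- make_cylinder_phantom(c(rep(10, 6), rep(20, 2)),
                               axis = c(0, 1, 0), spacing = 24,
                               shape = c(220, 24, 48), voxel_size = 1)
  m2 <- threshold_volume(ph2$volume, "fixed", value = 100)
  s2 <- sections_from_stack(resample_perpendicular(m2, c(0, 1, 0)))
  st2 <- density_and_stats(s2, 1)
  expect_equal(st2$d_e_peak, 10, tolerance = 1.5)
  expect_error(density_and_stats(s2[0, ], 1), "no sections")
})

test_that("single-fibre profiles follow the tube geometry", {
  # straight cylinder: constant profile at the true diameter
  ph <- make_cylinder_phantom(20, axis = c(0, 1, 0), spacing = 1,
                              shape = c(48, 72, 48), voxel_size = 1)
  m <- threshold_volume(ph$volume, "fixed", value = 100)
  pr <- single_fibre_profile(m)
  core <- pr$profile[pr$profile$arc > 10 & pr$profile$arc < max(pr$profile$arc) - 10, ]
  expect_lt(max(abs(core$d_e - 20)) / 20, 0.05)
  expect_gt(min(core$xi), 0.9)
  # cone: monotone d_e profile
  tpts <- seq(8, 56, by = 0.25)
  pts <- cbind(24, tpts, 24)
  radii <- seq(4, 12, length.out = length(tpts))
  cone <- array(fibrequant:::paint_balls_cpp(pts, radii, c(48L, 64L, 48L)),
                c(48, 64, 48))
  mc <- mask3d(cone, 1)
  prc <- single_fibre_profile(mc, centreline = cbind(24, seq(12, 52, 1), 24))
  fitslope <- coef(lm(d_e ~ arc, prc$profile))[2]
  expect_gt(fitslope, 0.1)
  # wavy tube of constant radius: flat d_e within 10%
  tw <- seq(4, 92, by = 0.25)
  wpts <- cbind(32 + 8 * sin(2 * pi * tw / 48), tw, 32)
  wavy <- array(fibrequant:::paint_balls_cpp(wpts, rep(8, length(tw)),
                                             c(64L, 96L, 64L)), c(64, 96, 64))
  cl <- cbind(32 + 8 * sin(2 * pi * seq(8, 88, 1) / 48), seq(8, 88, 1), 32)
  prw <- single_fibre_profile(mask3d(wavy, 1), centreline = cl)
  corew <- prw$profile[prw$profile$arc > 8 &
                       prw$profile$arc < max(prw$profile$arc) - 8, ]
  expect_lt((max(corew$d_e) - min(corew$d_e)) / 16, 0.10)
})
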