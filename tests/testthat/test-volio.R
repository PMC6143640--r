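test_that("raw and TIFF round-trips are lossless with intact metadata", {
  set.seed(1)
  vol <- volume3d(array(runif(32^3), c(32, 32, 32)), 13,
                  axes = c("y", "x", "z"))
  p <- file.path(withr::local_tempdir(), "v.raw")
  write_volume(vol, p, dtype = "float64")
  back <- read_volume(p)
  expect_identical(back$data, vol$data)
  expect_equal(back$voxel_size, 13)
  expect_identical(back$axes, c("y", "x", "z"))

  voli <- volume3d(array(sample(0:65535, 16^3, TRUE), c(16, 16, 16)), 2)
  pt <- file.path(withr::local_tempdir(), "v.tif")
  write_volume(voli, pt, dtype = "uint16")
  backt <- read_volume(pt)
  expect_identical(backt$data, voli$data)

  mk <- mask3d(array(runif(10^3) > 0.5, c(10, 10, 10)), 3)
  pm <- file.path(withr::local_tempdir(), "m.raw")
  write_volume(mk, pm)
  backm <- read_volume(pm)
  expect_s3_class(backm, "mask3d")
  expect_identical(backm$data, mk$data)
})

test_that("metadata failures are explicit", {
  d <- withr::local_tempdir()
  vol <- volume3d(array(1:27, c(3, 3, 3)), 1)
  p <- file.path(d, "v.raw")
  write_volume(vol, p, dtype = "float64")
  # corrupt the sidecar shape
  meta <- jsonlite::read_json(paste0(p, ".json"))
  meta$shape <- list(3, 3, 4)
  jsonlite::write_json(meta, paste0(p, ".json"), auto_unbox = TRUE)
  expect_error(read_volume(p), "does not match")
  # no sidecar at all -> no voxel size -> explicit failure
  file.remove(paste0(p, ".json"))
  expect_error(read_volume(p), "voxel size")
})

test_that("a directory of single-slice TIFFs stacks along z", {
  d <- withr::local_tempdir()
  set.seed(2)
  arr <- array(sample(0:255, 8 * 8 * 10, TRUE), c(8, 8, 10))
  for (k in 1:10)
    write_volume(volume3d(array(arr[, , k], c(8, 8, 1)), 5),
                 file.path(d, sprintf("slice_%02d.tif", k)),
                 dtype = "uint8")
  jsonlite::write_json(list(voxel_size_um = 5), file.path(d, "meta.json"),
                       auto_unbox = TRUE)
  vol <- read_volume(d)
  expect_equal(dim(vol$data)[3], 10)
  expect_identical(vol$data, arr)
})

test_that("thresholding matches generated foreground and Otsu lies between modes", {
  ph <- make_bead_phantom(rbind(c(20, 20, 20), c(40, 40, 40)), 6,
                          shape = c(64, 64, 64), fg = 200, bg = 50)
  truth <- ph$volume$data > 100
  expect_identical(threshold_volume(ph$volume, "otsu")$data, truth)
  expect_identical(threshold_volume(ph$volume, "fixed", value = 100)$data,
                   truth)
  expect_error(threshold_volume(volume3d(array(1, c(4, 4, 4)), 1), "otsu"),
               "non-constant")
  # two-Gaussian mixture: Otsu threshold separates the means
  set.seed(3)
  v <- array(c(rnorm(4000, 50, 8), rnorm(4000, 150, 8)), c(20, 20, 20))
  thr <- fibrequant:::otsu_threshold(as.vector(v))
  expect_gt(thr, 50)
  expect_lt(thr, 150)
})

test_that("morphological operations match brute-force ball morphology", {
  for (seed in 1:4) {
    d <- c(sample(8:14, 1), sample(8:14, 1), sample(8:14, 1))
    arr <- rand_mask(d, seed)
    for (r in c(1, 2)) {
      expect_identical(fibrequant:::morph_erode(arr, r), bf_erode(arr, r),
                       label = sprintf("erode seed=%d r=%d", seed, r))
      expect_identical(fibrequant:::morph_dilate(arr, r), bf_dilate(arr, r),
                       label = sprintf("dilate seed=%d r=%d", seed, r))
    }
  }
})

test_that("morph_clean plans behave per contract", {
  # isolated voxel removed by opening
  arr <- array(FALSE, c(9, 9, 9)); arr[5, 5, 5] <- TRUE
  m <- mask3d(arr, 1)
  expect_warning(res <- morph_clean(m, list(list(op = "open", r = 1))),
                 "empty")
  expect_false(any(res$data))
  # hollow ball filled solid
  co <- vox_coords(c(15, 15, 15))
  rr <- sqrt(rowSums((co - 7)^2))
  hollow <- array(rr <= 6 & rr >= 4, c(15, 15, 15))
  solid <- array(rr <= 6, c(15, 15, 15))
  filled <- morph_clean(mask3d(hollow, 1), list("fill_holes"))
  expect_identical(filled$data, solid)
  # opening a solid ball: nothing added, deep interior preserved
  op <- morph_clean(mask3d(solid, 1), list(list(op = "open", r = 2)))
  expect_true(all(solid[op$data]))
  deep <- array(rr <= 3, c(15, 15, 15))
  expect_true(all(op$data[deep]))
  # isolated voxel removed by median; bulk interior kept
  blk <- array(FALSE, c(12, 12, 12)); blk[3:10, 3:10, 3:10] <- TRUE
  blk[1, 1, 1] <- TRUE
  md <- morph_clean(mask3d(blk, 1), list(list(op = "median", r = 1)))
  expect_false(md$data[1, 1, 1])
  expect_true(all(md$data[4:9, 4:9, 4:9]))
  # provenance records the chain
  expect_match(md$provenance[length(md$provenance)], "median")
})

test_that("euclidean distance map follows the voxel-centre metric", {
  # slab of 21 voxels: mid-plane distance 11 * voxel size
  m <- mask3d(array(TRUE, c(25, 25, 21)), 13)
  dm <- euclidean_distance_map(m)
  expect_equal(dm$data[13, 13, 11], 11 * 13)
  # single foreground voxel
  one <- array(FALSE, c(7, 7, 7)); one[4, 4, 4] <- TRUE
  expect_equal(euclidean_distance_map(mask3d(one, 2.5))$data[4, 4, 4], 2.5)
  # all-foreground grid: grows from faces inward, max at centre
  full <- euclidean_distance_map(mask3d(array(TRUE, c(9, 9, 9)), 1))
  expect_equal(max(full$data), full$data[5, 5, 5])
  expect_true(all(full$data[1, , ] == 1))
  expect_error(euclidean_distance_map(mask3d(array(FALSE, c(4, 4, 4)), 1)),
               "empty")
})

test_that("distance map equals the brute-force oracle on random masks", {
  for (seed in 1:8) {
    d <- c(sample(5:20, 1), sample(5:20, 1), sample(5:20, 1))
    arr <- rand_mask(d, seed + 100, p = runif(1, 0.2, 0.8))
    if (!any(arr)) next
    dm <- euclidean_distance_map(mask3d(arr, 1))
    expect_identical(dm$data, bf_edt(arr),
                     label = sprintf("edt oracle seed=%d", seed))
  }
})

test_that("crop_roi uses 0-based half-open bounds and composes", {
  vol <- volume3d(array(1:(6 * 7 * 8), c(6, 7, 8)), 2)
  full <- crop_roi(vol, list(x = c(0, 6), y = c(0, 7), z = c(0, 8)))
  expect_equal(as.vector(full$data), as.vector(vol$data))
  c1 <- crop_roi(vol, list(x = c(1, 5), y = c(2, 7)))
  c2 <- crop_roi(c1, list(x = c(1, 3)))
  direct <- crop_roi(vol, list(x = c(2, 4), y = c(2, 7)))
  expect_equal(as.vector(c2$data), as.vector(direct$data))
  expect_equal(attr(c2$data, "origin_offset"), c(2, 2, 0))
  expect_equal(c2$voxel_size, 2)
  expect_error(crop_roi(vol, list(x = c(0, 9))), "invalid bounds")
  expect_error(crop_roi(vol, list(x = c(3, 3))), "invalid bounds")
})
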