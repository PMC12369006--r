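test_that("volumes round-trip through TIFF and NRRD at float32 precision", {
  g <- generate_cell(desk_wt(seed = 5))
  tomo <- g$tomogram

  tf <- withr::local_tempfile(fileext = ".tif")
  write_volume(tomo, tf)
  back <- read_volume(tf, voxel_size = tomo$voxel_size)
  expect_equal(dim(back$values), dim(tomo$values))
  expect_lt(max(abs(back$values - tomo$values)), 1e-6) # float32 rounding
  expect_identical(back$voxel_size, tomo$voxel_size)

  nf <- withr::local_tempfile(fileext = ".nrrd")
  write_volume(tomo, nf)
  back2 <- read_volume(nf) # voxel size from the NRRD header
  expect_lt(max(abs(back2$values - tomo$values)), 1e-6)
  expect_equal(back2$voxel_size, tomo$voxel_size)
})

test_that("missing voxel size and non-3D input are explicit errors", {
  g <- generate_cell(desk_wt(seed = 5))
  tf <- withr::local_tempfile(fileext = ".tif")
  write_volume(g$tomogram, tf)
  expect_error(read_volume(tf), "voxel size")

  flat <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 32, 32), flat)
  expect_error(read_volume(flat, voxel_size = 0.15), "single page")

  expect_error(ri_tomogram(array(1.4, c(20, 20)), 0.15), "3D")
  expect_error(ri_tomogram(array(0.9, c(20, 20, 20)), 0.15), "below 1")
  expect_error(ri_tomogram(array(1.4, c(20, 20, 20)), NA), "voxel size")
})

test_that("physical units propagate from NRRD metadata to measured volumes", {
  # digitized sphere of radius 3 um on a 0.25 um grid: voxel count times
  # voxel volume approximates 4/3 pi r^3, and survives an I/O round trip
  d <- c(48, 48, 48)
  vs <- 0.25
  ctr <- d * vs / 2
  zc <- (seq_len(d[1]) - 0.5) * vs
  sq <- outer(outer((zc - ctr[1])^2, (zc - ctr[2])^2, "+"), (zc - ctr[3])^2, "+")
  sphere <- array(sq <= 3^2, d)
  nuc <- array(FALSE, d); nuc[22:26, 22:26, 22:26] <- TRUE
  masks <- compartment_masks(sphere, nuc, array(FALSE, d), vs)
  nf <- withr::local_tempfile(fileext = ".nrrd")
  write_masks(masks, nf)
  back <- read_masks(nf)
  vol <- sum(back$cell) * prod(back$voxel_size)
  expect_equal(vol, sum(sphere) * vs^3)
  expect_equal(vol, 4 / 3 * pi * 3^3, tolerance = 0.02)
})

test_that("mask label volumes encode and round-trip the three compartments", {
  g <- generate_cell(desk_ko(seed = 6))
  m <- g$truth$masks
  lab <- masks_to_labels(m)
  expect_setequal(unique(as.vector(lab)), c(0L, 1L, 2L, 3L))
  m2 <- labels_to_masks(lab, m$voxel_size)
  expect_identical(m2$cell, m$cell)
  expect_identical(m2$nucleus, m$nucleus)
  expect_identical(m2$lvc, m$lvc)

  nf <- withr::local_tempfile(fileext = ".nrrd")
  write_masks(m, nf)
  m3 <- read_masks(nf)
  expect_identical(m3$lvc, m$lvc)
  expect_equal(m3$voxel_size, m$voxel_size)

  tf <- withr::local_tempfile(fileext = ".tif")
  write_masks(m, tf)
  m4 <- read_masks(tf, voxel_size = m$voxel_size)
  expect_identical(m4$nucleus, m$nucleus)

  bad <- lab; bad[1, 1, 1] <- 7L
  expect_error(labels_to_masks(bad, m$voxel_size), "unknown label")
})

test_that("mask invariants are enforced and empty LVC is legal but flagged", {
  d <- c(20, 20, 20)
  cell <- array(TRUE, d)
  nuc <- array(FALSE, d); nuc[8:12, 8:12, 8:12] <- TRUE
  lvc <- array(FALSE, d); lvc[10, 10, 15] <- TRUE
  overlap <- lvc; overlap[10, 10, 10] <- TRUE
  expect_error(compartment_masks(cell, nuc, overlap, 0.2), "overlap")
  outside <- array(FALSE, d); outside[1, 1, 1] <- TRUE
  expect_error(compartment_masks(cell & !outside, nuc, outside, 0.2),
               "outside the cell")
  empty <- compartment_masks(cell, nuc, array(FALSE, d), 0.2)
  expect_true("empty_lvc" %in% empty$flags)
})
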