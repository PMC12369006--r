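test_that("noiseless phantoms are segmented essentially exactly", {
  g <- generate_cell(desk_wt(noise_sd = 0, seed = 7))
  m <- segment_tomogram(g$tomogram)
  expect_equal(dice(m$cell, g$truth$masks$cell), 1.0)
  expect_gte(dice(m$nucleus, g$truth$masks$nucleus), 0.85)

  gk <- generate_cell(desk_ko(noise_sd = 0, seed = 3))
  mk <- segment_tomogram(gk$tomogram)
  expect_gte(dice(mk$lvc, gk$truth$masks$lvc), 0.9)
})

test_that("noisy phantoms keep high Dice against ground truth", {
  dn <- dc <- numeric(0)
  for (s in 1:10) {
    g <- generate_cell(desk_wt(seed = s)) # default noise_sd = 0.004
    m <- segment_tomogram(g$tomogram)
    dc <- c(dc, dice(m$cell, g$truth$masks$cell))
    dn <- c(dn, dice(m$nucleus, g$truth$masks$nucleus))
  }
  expect_gte(min(dc), 0.98)
  expect_gte(median(dn), 0.8)
})

test_that("rough LVC keeps the expected cellular voxel fraction", {
  g <- generate_cell(desk_wt(seed = 11))
  cm <- segment_cell(g$tomogram)
  rl <- rough_lvc(g$tomogram, cm)
  frac <- sum(rl$mask) / sum(cm)
  expect_lt(abs(frac - 0.20), 0.01)
  # threshold is strictly exceeded
  expect_true(all(g$tomogram$values[rl$mask] > rl$threshold))
  # q -> 0 limit recovers the whole cell
  rl0 <- rough_lvc(g$tomogram, cm, segmentation_config(lvc_quantile = 1e-6))
  expect_gt(sum(rl0$mask) / sum(cm), 0.999)
})

test_that("rough LVC engulfs all true lysosomal voxels when they are rare", {
  g <- generate_cell(desk_ko(noise_sd = 0, seed = 13))
  truth <- g$truth$masks
  expect_lt(sum(truth$lvc) / sum(truth$cell), 0.2)
  cm <- segment_cell(g$tomogram)
  rl <- rough_lvc(g$tomogram, cm)
  expect_true(all(rl$mask[truth$lvc]))
})

test_that("per-cell thresholding is invariant to a constant RI shift", {
  g <- generate_cell(desk_wt(seed = 17))
  cfg <- segmentation_config(cell_threshold_mode = "otsu")
  m1 <- segment_tomogram(g$tomogram, cfg)
  shifted <- ri_tomogram(g$tomogram$values + 0.01, g$tomogram$voxel_size)
  m2 <- segment_tomogram(shifted, cfg)
  expect_identical(m1$cell, m2$cell)
  expect_identical(m1$nucleus, m2$nucleus)
  expect_identical(m1$lvc, m2$lvc)
})

test_that("reference cube sits centrally and avoids the rough LVC", {
  g <- generate_cell(desk_wt(seed = 19))
  cm <- segment_cell(g$tomogram)
  rl <- rough_lvc(g$tomogram, cm)
  ref <- select_reference_cube(g$tomogram, cm, rl$mask)
  rg <- attr(ref, "voxel_ranges")
  # concentric phantom, no central lysosomes: cube lies inside true nucleus
  expect_true(all(g$truth$masks$nucleus[rg[[1]], rg[[2]], rg[[3]]]))
  expect_false(any(rl$mask[rg[[1]], rg[[2]], rg[[3]]]))

  # plant rough-LVC voxels over the central cubes: selection must move off
  # centre but stay LVC-free
  planted <- rl$mask
  ctr <- round(dim(planted) / 2)
  planted[(ctr[1] - 5):(ctr[1] + 5), (ctr[2] - 5):(ctr[2] + 5),
          (ctr[3] - 5):(ctr[3] + 5)] <- TRUE
  ref2 <- select_reference_cube(g$tomogram, cm, planted)
  rg2 <- attr(ref2, "voxel_ranges")
  expect_false(any(planted[rg2[[1]], rg2[[2]], rg2[[3]]]))
  expect_false(identical(as.integer(ref), as.integer(ref2)))

  # no admissible cube at all -> explicit error
  expect_error(select_reference_cube(g$tomogram, cm, cm),
               "smaller")
})

test_that("LVC refinement subtracts the nucleus and prunes small components", {
  d <- c(30, 30, 30)
  nuc <- array(FALSE, d); nuc[10:20, 10:20, 10:20] <- TRUE
  # rough entirely outside the nucleus: identity up to small components
  rough <- array(FALSE, d)
  rough[2:5, 2:5, 2:5] <- TRUE          # 64 voxels, kept
  rough[25, 25, 25] <- TRUE             # singleton, pruned
  out <- refine_lvc(rough, nuc)
  expect_true(all(out[2:5, 2:5, 2:5]))
  expect_false(out[25, 25, 25])

  # rough inside the nucleus: empty result, flagged
  inside <- array(FALSE, d); inside[12:15, 12:15, 12:15] <- TRUE
  out2 <- refine_lvc(inside, nuc)
  expect_false(any(out2))
  expect_true("empty_lvc" %in% attr(out2, "flags"))
  expect_false(any(out & nuc))
})

test_that("all-medium volume and no-contrast nucleus are reported", {
  vol <- array(1.334, c(32, 32, 32))
  expect_error(segment_cell(ri_tomogram(vol + rnorm(length(vol), 0, 1e-5), 0.2)),
               "no cell found")

  # nucleus RI equal to cytoplasm (noiseless): CSSI cannot tell the interior
  # apart, floods the cell and flags it
  d <- c(48, 48, 48); vs <- 0.2; ctr <- d * vs / 2
  zc <- (seq_len(48) - 0.5) * vs
  sq <- outer(outer((zc - ctr[1])^2, (zc - ctr[2])^2, "+"), (zc - ctr[3])^2, "+")
  cellm <- array(sq <= 4^2, d)
  blob <- array(outer(outer((zc - ctr[1])^2, (zc - ctr[2])^2, "+"),
                      (zc - ctr[3] - 2)^2, "+") <= 0.6^2, d)
  vol <- array(1.334, d); vol[cellm] <- 1.355; vol[blob & cellm] <- 1.395
  m <- segment_tomogram(ri_tomogram(vol, vs))
  expect_true("nucleus_floods_cell" %in% m$flags)
})

test_that("segmentation output always satisfies the mask invariants", {
  for (s in c(29, 31)) {
    g <- generate_cell(if (s %% 2) desk_wt(seed = s) else desk_ko(seed = s))
    m <- segment_tomogram(g$tomogram)
    expect_s3_class(m, "compartment_masks")
    expect_false(any(m$nucleus & m$lvc))
    expect_false(any(m$nucleus & !m$cell))
    expect_false(any(m$lvc & !m$cell))
    prov <- attr(m, "provenance")
    expect_true(is.numeric(prov$lvc_threshold))
    expect_length(prov$reference_cube, 3)
  }
})
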