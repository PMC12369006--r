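test_that("analytic solid-angle and half-space cases are exact", {
  # closed concentric shell: every direction cell is occupied
  gs <- generate_cell(desk_shell(seed = 2))
  expect_identical(compute_nlnsa(gs$truth$masks), 1)

  # fully one-sided aggregate: HLVR = 1
  gp <- generate_cell(desk_ko(kappa = 50, noise_sd = 0, seed = 5))
  expect_identical(compute_hlvr(gp$truth$masks)[["plus"]], 1)

  # mirror-symmetric two-voxel LVC about the nucleus centroid: 0.5
  m_sym <- box_masks(lvc_index = rbind(c(24, 24, 10), c(24, 24, 38)))
  expect_identical(compute_hlvr(m_sym)[["plus"]], 0.5)

  # single LVC voxel occupies exactly one of 1280 direction cells
  m_one <- box_masks(lvc_index = rbind(c(24, 24, 40)))
  expect_identical(compute_nlnsa(m_one), 1 / 1280)

  # concentric phantom: nucleus-cell centroid distance vanishes
  expect_lt(compute_nnccd(gs$truth$masks), 0.01)
})

test_that("hemispheric coverage measures half the sphere", {
  gs <- generate_cell(desk_shell(seed = 2))
  m <- gs$truth$masks
  cn <- which(m$nucleus, arr.ind = TRUE)
  z_cut <- mean(cn[, 1])
  hemi <- m$lvc
  idx <- which(hemi, arr.ind = TRUE)
  hemi[idx[idx[, 1] <= z_cut, , drop = FALSE]] <- FALSE
  mh <- compartment_masks(m$cell, m$nucleus, hemi, m$voxel_size)
  expect_lt(abs(compute_nlnsa(mh) - 0.5), 0.02)
})

test_that("HLVR equals brute-force half-space counting", {
  # constructed 70/30 split: 70 voxels far +x, 30 voxels at -x
  lvc_idx <- rbind(
    as.matrix(expand.grid(i = 20:26, j = 21:30, k = 40)),  # 70 voxels +x side
    as.matrix(expand.grid(i = 22:24, j = 22:31, k = 8))    # 30 voxels -x side
  )
  colnames(lvc_idx) <- NULL
  m <- box_masks(lvc_index = lvc_idx)
  got <- compute_hlvr(m)[["plus"]]
  expect_identical(got, brute_hlvr(m))
  expect_identical(got, 0.7)

  # random phantoms: exact agreement with the enumeration oracle
  for (s in 1:3) {
    g <- generate_cell(desk_ko(seed = s))
    h <- compute_hlvr(g$truth$masks)
    expect_identical(h[["plus"]], brute_hlvr(g$truth$masks))
    expect_identical(h[["plus"]] + h[["minus"]], 1)
  }
})

test_that("PSSE matches a brute-force histogram oracle and its invariants", {
  # identical compartments: zero divergence
  set.seed(31)
  pts <- cbind(runif(300, 0, 5), runif(300, 0, 5), runif(300, 0, 5))
  expect_equal(compute_psse(pts, pts, c(2.5, 2.5, 2.5))[["azel"]], 0)

  # fixed 200-voxel toy: one-pole cap vs isotropic cloud
  u <- matrix(rnorm(600), ncol = 3); u <- u / sqrt(rowSums(u^2))
  iso <- u * runif(200, 1, 2)
  cap <- abs(u) * runif(200, 1, 2) # first octant: strongly anisotropic
  org <- c(0, 0, 0)
  got <- compute_psse(cap, iso, org)
  want <- brute_psse(cap, iso, org)
  expect_equal(got[["az"]], want[["az"]], tolerance = 1e-12)
  expect_equal(got[["el"]], want[["el"]], tolerance = 1e-12)
  expect_equal(got[["azel"]], got[["az"]] + got[["el"]])

  # two isotropic shells at different radii: divergence near zero
  set.seed(33)
  u1 <- matrix(rnorm(3e4), ncol = 3); u1 <- u1 / sqrt(rowSums(u1^2))
  u2 <- matrix(rnorm(3e4), ncol = 3); u2 <- u2 / sqrt(rowSums(u2^2))
  psse_iso <- compute_psse(u1 * 1.0, u2 * 2.0, org)
  expect_lt(psse_iso[["azel"]], 5)
})

test_that("NNCCD recovers a constructed displacement of half the radius", {
  d <- c(64, 64, 64); vs <- 0.2; ctr <- d * vs / 2
  zc <- (seq_len(64) - 0.5) * vs
  sq <- outer(outer((zc - ctr[1])^2, (zc - ctr[2])^2, "+"), (zc - ctr[3])^2, "+")
  cellm <- array(sq <= 5^2, d)
  r_eq <- (3 * sum(cellm) * vs^3 / (4 * pi))^(1 / 3)
  off <- r_eq / 2
  sqn <- outer(outer((zc - ctr[1])^2, (zc - ctr[2])^2, "+"),
               (zc - ctr[3] - off)^2, "+")
  nucm <- array(sqn <= 1.2^2, d) & cellm
  m <- compartment_masks(cellm, nucm, array(FALSE, d), vs)
  expect_lt(abs(compute_nnccd(m) - 0.5), 0.01)
})

test_that("feature extraction emits 17 tagged features deterministically", {
  reg <- feature_registry()
  expect_identical(nrow(reg), 17L)
  expect_identical(sum(reg$biomarker == "lys-nuc"), 7L)
  expect_identical(sum(reg$biomarker == "nuc-cell"), 5L)
  expect_identical(sum(reg$biomarker == "lys-cell"), 5L)
  expect_setequal(unique(reg$frame), c("cartesian", "spherical"))

  g <- generate_cell(desk_ko(seed = 8))
  fv1 <- compute_features(g$truth$masks)
  fv2 <- compute_features(g$truth$masks)
  expect_identical(fv1$features, fv2$features)
  expect_length(fv1$features, 17)
  expect_identical(names(fv1$features), reg$feature)
  expect_true(all(is.finite(fv1$features)))
  # range invariants
  expect_true(fv1$features[["NLNSA"]] >= 0 && fv1$features[["NLNSA"]] <= 1)
  expect_true(fv1$features[["HLVR"]] >= 0 && fv1$features[["HLVR"]] <= 1)
  expect_true(all(fv1$features[c("LNPSSE_AzEl", "NCPSSE_AzEl", "LCPSSE_AzEl")] >= 0))
  expect_true(fv1$features[["NCVR"]] > 0 && fv1$features[["NCVR"]] < 1)
  expect_true(fv1$features[["LVF"]] > 0 && fv1$features[["LVF"]] < 1)
  expect_lte(fv1$features[["NSPH"]], 1.1)
  expect_equal(fv1$aux[["HLVR_minus"]], 1 - fv1$features[["HLVR"]])
})

test_that("an empty LVC propagates missing values without aborting", {
  g <- generate_cell(desk_wt(n_lysosome_blobs = 0, seed = 9))
  fv <- compute_features(g$truth$masks)
  expect_true("empty_lvc" %in% fv$flags)
  reg <- feature_registry()
  lvc_feats <- reg$feature[reg$biomarker != "nuc-cell"]
  expect_true(all(is.na(fv$features[lvc_feats])))
  expect_true(all(is.finite(fv$features[reg$feature[reg$biomarker == "nuc-cell"]])))
  # empty cell or nucleus is an error instead
  d <- dim(g$truth$masks$cell)
  expect_error(compute_features(
    compartment_masks(g$truth$masks$cell, array(FALSE, d), array(FALSE, d),
                      g$truth$masks$voxel_size)), "nucleus")
})

test_that("features are translation-invariant and NLNSA rotation-stable", {
  g <- generate_cell(desk_ko(seed = 12))
  m <- g$truth$masks
  shift <- function(a, k) {
    out <- array(FALSE, dim(a))
    d <- dim(a)
    out[(1 + k):d[1], , ] <- a[1:(d[1] - k), , ]
    out
  }
  k <- 3L
  m_sh <- compartment_masks(shift(m$cell, k), shift(m$nucleus, k),
                            shift(m$lvc, k), m$voxel_size)
  f0 <- compute_features(m)$features
  f1 <- compute_features(m_sh)$features
  expect_equal(f0, f1, tolerance = 1e-8)

  # exact 90-degree rotation about the z axis
  rot90 <- function(a) aperm(a[, , rev(seq_len(dim(a)[3]))], c(1, 3, 2))
  m_rot <- compartment_masks(rot90(m$cell), rot90(m$nucleus), rot90(m$lvc),
                             m$voxel_size)
  expect_lt(abs(compute_nlnsa(m) - compute_nlnsa(m_rot)), 0.02)
})

test_that("NLNSA agrees with a Monte-Carlo ray-casting oracle", {
  for (s in c(4, 14)) {
    g <- generate_cell(desk_ko(seed = s))
    m <- g$truth$masks
    cn <- unname(colMeans(which(m$nucleus, arr.ind = TRUE)))
    origin <- c((cn[3] - 0.5) * m$voxel_size[3], (cn[2] - 0.5) * m$voxel_size[2],
                (cn[1] - 0.5) * m$voxel_size[1])
    mc <- mc_solid_angle(m$lvc, m$voxel_size, origin, n_rays = 2e5, seed = s)
    expect_lt(abs(compute_nlnsa(m) - mc), 0.02)
  }
})

test_that("solid-angle partition resolution is a second-order effect", {
  g <- generate_cell(desk_ko(seed = 21))
  n1 <- compute_nlnsa(g$truth$masks, n_directions = 1280)
  n2 <- compute_nlnsa(g$truth$masks, n_directions = 5120)
  expect_lt(abs(n1 - n2), 0.03)
  dirs <- icosphere_directions(1280)
  expect_identical(nrow(dirs), 1280L)
  expect_equal(max(abs(rowSums(dirs^2) - 1)), 0, tolerance = 1e-12)
})
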