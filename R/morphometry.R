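#' Registry of the 17 morphometric features
#'
#' Each feature is tagged with the biomarker it belongs to (`lys-nuc`,
#' `nuc-cell`, `lys-cell`) and the coordinate frame it is computed in
#' (`cartesian`, `spherical`).
#'
#' @return data.frame with columns `feature`, `biomarker`, `frame`.
#' @export
feature_registry <- function() {
  data.frame(
    feature = c("NLNSA", "HLVR", "LNPSSE_AzEl", "LNPSSE_Az", "LNPSSE_El",
                "LNCCD", "LNRG",
                "NNCCD", "NSPH", "NCVR", "NCPSSE_AzEl", "NRP",
                "LCPSSE_AzEl", "LVF", "LRM", "LCMP", "LCCCD"),
    biomarker = c(rep("lys-nuc", 7), rep("nuc-cell", 5), rep("lys-cell", 5)),
    frame = c("cartesian", "cartesian", "spherical", "spherical", "spherical",
              "cartesian", "spherical",
              "cartesian", "cartesian", "cartesian", "spherical", "spherical",
              "spherical", "cartesian", "spherical", "cartesian", "cartesian"),
    stringsAsFactors = FALSE
  )
}

#' Half-nuclear lysosome volume ratio (HLVR)
#'
#' The plane through the nucleus centroid, orthogonal to the segment joining
#' the nucleus centroid to the LVC centroid, splits space into the half
#' containing the LVC centroid (+) and the other half (-). HLVR+ is the
#' fraction of LVC voxels in the + half-space; HLVR- = 1 - HLVR+. 0.5 means
#' lysosomes surround the nucleus uniformly; 1 means full one-sided
#' accumulation. Computed in physical (um) coordinates. When the two
#' centroids coincide (within 1e-9 um) the direction is undefined and 0.5 is
#' returned by convention.
#'
#' @param masks a [compartment_masks()] with nonempty nucleus and LVC.
#' @return named numeric `c(plus = , minus = )`; `NA` if the LVC is empty.
#' @export
compute_hlvr <- function(masks) {
  stopifnot(inherits(masks, "compartment_masks"))
  if (!any(masks$lvc)) return(c(plus = NA_real_, minus = NA_real_))
  if (!any(masks$nucleus)) stop("nucleus mask is empty", call. = FALSE)
  vs <- masks$voxel_size
  c_n <- mask_centroid(masks$nucleus, vs)
  pts <- voxel_coords(masks$lvc, vs)
  c_l <- colMeans(pts)
  n_vec <- c_l - c_n
  nn <- sqrt(sum(n_vec^2))
  if (nn < 1e-9) return(c(plus = 0.5, minus = 0.5))
  n_vec <- n_vec / nn
  side <- as.vector(sweep(pts, 2, c_n, "-") %*% n_vec) >= 0
  plus <- mean(side)
  c(plus = plus, minus = 1 - plus)
}

#' Normalized lysosome-nucleus solid angle (NLNSA)
#'
#' Fraction of the full 4*pi sphere of directions from the nucleus centroid
#' that is subtended by the LVC. The unit sphere is partitioned into
#' `n_directions` approximately equal-area cells (subdivided icosahedron);
#' a cell counts as occupied when the direction of at least one LVC voxel
#' centre falls in it. 1 = lysosomes fully surround the nucleus; values near
#' 0 = tight one-pole accumulation.
#'
#' @param masks a [compartment_masks()] with nonempty nucleus and LVC.
#' @param n_directions number of direction cells (`20 * f^2`). Default 1280.
#' @return numeric in `[0, 1]`; `NA` if the LVC is empty.
#' @export
compute_nlnsa <- function(masks, n_directions = 1280) {
  stopifnot(inherits(masks, "compartment_masks"))
  if (!any(masks$lvc)) return(NA_real_)
  if (!any(masks$nucleus)) stop("nucleus mask is empty", call. = FALSE)
  vs <- masks$voxel_size
  c_n <- mask_centroid(masks$nucleus, vs)
  pts <- voxel_coords(masks$lvc, vs)
  dirs <- unit_rows(sweep(pts, 2, c_n, "-"))
  if (nrow(dirs) == 0L) return(NA_real_)
  centers <- icosphere_directions(n_directions)
  cells <- assign_direction_cells(dirs, centers)
  length(unique(cells)) / n_directions
}

#' Percentage sum of squared error (PSSE) between angular distributions
#'
#' Converts the voxel centres of two compartments to spherical coordinates
#' about a common origin, histograms azimuth (uniform bins over
#' `[-pi, pi]`) and elevation (bins uniform in `sin(elevation)`, i.e. equal
#' solid angle, so an isotropic cloud is flat in both), normalizes each
#' histogram to unit sum, and reports
#' `PSSE = 100 * sum((p - q)^2) / sum(q^2)` per coordinate, where `p` is
#' compartment A's histogram and `q` the reference compartment B's. The
#' combined Az-El value is the sum of the two.
#'
#' @param points_a,points_b `m x 3` matrices of (x, y, z) voxel centres (um).
#' @param origin length-3 origin (um); nucleus centroid for lysosome-nucleus
#'   and lysosome-cytoplasm variants, cell centroid for nucleus-cell.
#' @param n_bins_az,n_bins_el histogram resolutions (defaults 36 and 18).
#' @return named numeric `c(az = , el = , azel = )`.
#' @export
compute_psse <- function(points_a, points_b, origin,
                         n_bins_az = 36, n_bins_el = 18) {
  if (nrow(points_a) == 0L || nrow(points_b) == 0L)
    return(c(az = NA_real_, el = NA_real_, azel = NA_real_))
  sph_a <- to_spherical(points_a, origin)
  sph_b <- to_spherical(points_b, origin)
  az_breaks <- seq(-pi, pi, length.out = n_bins_az + 1)
  el_breaks <- asin(seq(-1, 1, length.out = n_bins_el + 1))
  hist_norm <- function(x, breaks) {
    h <- tabulate(findInterval(x, breaks, all.inside = TRUE),
                  nbins = length(breaks) - 1L)
    h / sum(h)
  }
  psse_1d <- function(a, b, breaks) {
    p <- hist_norm(a, breaks)
    q <- hist_norm(b, breaks)
    100 * sum((p - q)^2) / sum(q^2)
  }
  az <- psse_1d(sph_a[, "azimuth"], sph_b[, "azimuth"], az_breaks)
  el <- psse_1d(sph_a[, "elevation"], sph_b[, "elevation"], el_breaks)
  c(az = az, el = el, azel = az + el)
}

#' Normalized nucleus-cell centroid distance (NNCCD)
#'
#' Euclidean distance between the nucleus and cell centroids, divided by the
#' cell's equivalent radius `(3 V_cell / 4 pi)^(1/3)`. 0 for a concentric
#' nucleus; grows as the nucleus is pushed toward the membrane.
#'
#' @param masks a [compartment_masks()] with nonempty cell and nucleus.
#' @return nonnegative numeric.
#' @export
compute_nnccd <- function(masks) {
  stopifnot(inherits(masks, "compartment_masks"))
  if (!any(masks$nucleus)) stop("nucleus mask is empty", call. = FALSE)
  vs <- masks$voxel_size
  c_c <- mask_centroid(masks$cell, vs)
  c_n <- mask_centroid(masks$nucleus, vs)
  sqrt(sum((c_n - c_c)^2)) / equivalent_radius(masks$cell, vs)
}

# volume of a circumscribing support polytope of the mask's voxel centres,
# evaluated on the voxel grid: x is inside iff d_k . x <= max_p d_k . p for
# all n_dirs well-spread directions. Overestimates the convex hull volume
# slightly (documented in the vignette); used by the LCMP compactness.
support_polytope_volume <- function(mask, voxel_size, n_dirs = 320,
                                    chunk = 20000L) {
  pts <- voxel_coords(mask, voxel_size)
  dirs <- icosphere_directions(n_dirs)
  h <- apply(pts %*% t(dirs), 2, max)
  # candidate voxels: bounding box of the mask
  idx <- which(mask, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  bb <- array(FALSE, dim(mask))
  bb[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  cand <- voxel_coords(bb, voxel_size)
  inside <- logical(nrow(cand))
  for (start in seq(1L, nrow(cand), by = chunk)) {
    end <- min(start + chunk - 1L, nrow(cand))
    proj <- cand[start:end, , drop = FALSE] %*% t(dirs)
    inside[start:end] <- rowSums(sweep(proj, 2, h + 1e-9, ">")) == 0L
  }
  sum(inside) * prod(voxel_size)
}

# directional cell-boundary radius from `origin` along unit vector `u`
# (physical um), found by marching until the ray leaves the cell mask
directional_radius <- function(mask, voxel_size, origin, u) {
  step <- 0.25 * min(voxel_size)
  d <- dim(mask)
  r <- 0
  repeat {
    r_next <- r + step
    p <- origin + r_next * u # x, y, z
    i <- ceiling(p[3] / voxel_size[1])
    j <- ceiling(p[2] / voxel_size[2])
    k <- ceiling(p[1] / voxel_size[3])
    if (i < 1 || j < 1 || k < 1 || i > d[1] || j > d[2] || k > d[3] ||
        !mask[i, j, k]) return(r)
    r <- r_next
  }
}

#' Compute the 17 morphometric features for one cell
#'
#' Extracts all lysosome-nucleus, nucleus-cell and lysosome-cell features
#' from a set of compartment masks, in physical (um) coordinates. An empty
#' LVC makes every LVC-dependent feature `NA` and flags the result; an empty
#' cell or nucleus is an error.
#'
#' Feature summary (see [feature_registry()] for taxonomy):
#' * `NLNSA` - normalized lysosome-nucleus solid angle ([compute_nlnsa()]).
#' * `HLVR` - half-nuclear lysosome volume ratio, + half ([compute_hlvr()]).
#' * `LNPSSE_Az`, `LNPSSE_El`, `LNPSSE_AzEl` - PSSE of the LVC vs nucleus
#'   angular distributions about the nucleus centroid.
#' * `LNCCD` - lysosome-nucleus centroid distance / cell equivalent radius.
#' * `LNRG` - mean radial gap of LVC voxels beyond the nucleus equivalent
#'   radius, / cell equivalent radius.
#' * `NNCCD` - normalized nucleus-cell centroid distance ([compute_nnccd()]).
#' * `NSPH` - nucleus sphericity `pi^(1/3) (6 V)^(2/3) / A` (voxel-face
#'   surface estimate with isotropic-staircase correction 2/3).
#' * `NCVR` - nucleus / cell volume ratio.
#' * `NCPSSE_AzEl` - PSSE of nucleus vs cell about the cell centroid.
#' * `NRP` - radial position of the nucleus centroid over the directional
#'   cell radius (cell-centred spherical frame).
#' * `LCPSSE_AzEl` - PSSE of LVC vs cytoplasm about the nucleus centroid.
#' * `LVF` - LVC / cell volume fraction.
#' * `LRM` - mean radial coordinate of LVC voxels about the cell centroid,
#'   / cell equivalent radius.
#' * `LCMP` - LVC compactness: volume / convex-hull (support-polytope)
#'   volume.
#' * `LCCCD` - lysosome-cell centroid distance / cell equivalent radius.
#'
#' @param masks a [compartment_masks()].
#' @param n_directions direction cells for NLNSA. Default 1280.
#' @param n_hull_directions supporting planes for the LCMP hull volume.
#'   Default 320.
#' @return object of class `feature_vector`: list with `features` (named
#'   numeric, length 17), `aux` (named numeric: `HLVR_minus`, volumes in
#'   um^3, centroids in um) and `flags` (character).
#' @export
compute_features <- function(masks, n_directions = 1280,
                             n_hull_directions = 320) {
  stopifnot(inherits(masks, "compartment_masks"))
  if (!any(masks$cell)) stop("cell mask is empty", call. = FALSE)
  if (!any(masks$nucleus)) stop("nucleus mask is empty", call. = FALSE)
  vs <- masks$voxel_size
  flags <- masks$flags

  c_cell <- mask_centroid(masks$cell, vs)
  c_nuc <- mask_centroid(masks$nucleus, vs)
  v_cell <- mask_volume(masks$cell, vs)
  v_nuc <- mask_volume(masks$nucleus, vs)
  r_cell <- equivalent_radius(masks$cell, vs)
  r_nuc <- equivalent_radius(masks$nucleus, vs)

  nuc_pts <- voxel_coords(masks$nucleus, vs)
  cell_pts <- voxel_coords(masks$cell, vs)

  f <- setNames(rep(NA_real_, 17), feature_registry()$feature)

  # nucleus-cell biomarker (always available)
  f["NNCCD"] <- sqrt(sum((c_nuc - c_cell)^2)) / r_cell
  area_nuc <- (2 / 3) * exposed_faces(masks$nucleus) *
    (vs[1] * vs[2] + vs[1] * vs[3] + vs[2] * vs[3]) / 3
  f["NSPH"] <- pi^(1 / 3) * (6 * v_nuc)^(2 / 3) / area_nuc
  f["NCVR"] <- v_nuc / v_cell
  f["NCPSSE_AzEl"] <- compute_psse(nuc_pts, cell_pts, c_cell)[["azel"]]
  off <- c_nuc - c_cell
  off_n <- sqrt(sum(off^2))
  f["NRP"] <- if (off_n < 1e-9) 0 else {
    rb <- directional_radius(masks$cell, vs, c_cell, off / off_n)
    if (rb > 0) off_n / rb else NA_real_
  }

  v_lvc <- mask_volume(masks$lvc, vs)
  c_lvc <- c(NA_real_, NA_real_, NA_real_)
  if (any(masks$lvc)) {
    lvc_pts <- voxel_coords(masks$lvc, vs)
    c_lvc <- colMeans(lvc_pts)

    f["NLNSA"] <- compute_nlnsa(masks, n_directions)
    f["HLVR"] <- compute_hlvr(masks)[["plus"]]
    ln <- compute_psse(lvc_pts, nuc_pts, c_nuc)
    f["LNPSSE_Az"] <- ln[["az"]]; f["LNPSSE_El"] <- ln[["el"]]
    f["LNPSSE_AzEl"] <- ln[["azel"]]
    f["LNCCD"] <- sqrt(sum((c_lvc - c_nuc)^2)) / r_cell
    r_from_nuc <- to_spherical(lvc_pts, c_nuc)[, "r"]
    f["LNRG"] <- mean(r_from_nuc - r_nuc) / r_cell

    cyto <- masks$cell & !masks$nucleus & !masks$lvc
    cyto_pts <- voxel_coords(cyto, vs)
    f["LCPSSE_AzEl"] <- compute_psse(lvc_pts, cyto_pts, c_nuc)[["azel"]]
    f["LVF"] <- v_lvc / v_cell
    f["LRM"] <- mean(to_spherical(lvc_pts, c_cell)[, "r"]) / r_cell
    hull_v <- support_polytope_volume(masks$lvc, vs, n_hull_directions)
    f["LCMP"] <- v_lvc / hull_v
    f["LCCCD"] <- sqrt(sum((c_lvc - c_cell)^2)) / r_cell
  } else {
    flags <- union(flags, "empty_lvc")
  }

  aux <- c(HLVR_minus = if (is.na(f[["HLVR"]])) NA_real_ else 1 - f[["HLVR"]],
           volume_cell_um3 = v_cell, volume_nucleus_um3 = v_nuc,
           volume_lvc_um3 = v_lvc,
           centroid_cell_x = c_cell[[1]], centroid_cell_y = c_cell[[2]],
           centroid_cell_z = c_cell[[3]],
           centroid_nucleus_x = c_nuc[[1]], centroid_nucleus_y = c_nuc[[2]],
           centroid_nucleus_z = c_nuc[[3]],
           centroid_lvc_x = c_lvc[[1]], centroid_lvc_y = c_lvc[[2]],
           centroid_lvc_z = c_lvc[[3]])
  structure(list(features = f, aux = aux, flags = flags),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("<feature_vector> 17 morphometric features\n")
  print(round(x$features, 4))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.feature_vector <- function(x, row.names = NULL, optional = FALSE, ...) {
  df <- as.data.frame(as.list(c(x$features, x$aux)))
  df$flags <- paste(x$flags, collapse = ";")
  df
}
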