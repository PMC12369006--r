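#' Segmentation configuration
#'
#' Parameters of the three-stage intracellular segmentation.
#'
#' @param lvc_quantile per-cell RI quantile above which cellular voxels enter
#'   the rough lysosomal volume (strictly greater-than comparison). The 0.80
#'   default keeps the top 20 percent of cellular RI values, exploiting the
#'   fact that lysosomes are the highest-RI structures in the cell.
#' @param cssi_cube_side side `eps` (voxels) of the non-overlapping cubes the
#'   volume is partitioned into for statistical region growing; `eps^3` RI
#'   values per cube. Default 5.
#' @param cssi_alpha significance level: a candidate cube joins the nucleus
#'   when the two-sample Kolmogorov-Smirnov p-value against the reference
#'   sample is >= `cssi_alpha`. Default 0.05.
#' @param cssi_max_iter maximum region-growing passes (the reference sample
#'   is re-pooled between passes). Default 10.
#' @param cell_threshold_mode `"fixed"` (medium RI + margin, default) or
#'   `"otsu"` (bimodal threshold on the full volume).
#' @param medium_ri,medium_margin fixed-mode threshold: voxels with
#'   RI > `medium_ri + medium_margin` are foreground. Defaults 1.334 + 0.004.
#' @param cssi_refine_band central quantile band of the reference RI sample
#'   used for voxel-level boundary recovery after cube-level growth (the
#'   accepted region grows by 6-connected steps into voxels whose RI lies in
#'   this band, for up to `cssi_cube_side` steps, undoing the epsilon-cube
#'   quantization of the nuclear boundary). Default 0.9.
#' @param min_component_voxels connected LVC components smaller than this are
#'   discarded during refinement. Default 27 (a 3x3x3 cube).
#' @return an object of class `segmentation_config`.
#' @export
segmentation_config <- function(lvc_quantile = 0.80, cssi_cube_side = 5,
                                cssi_alpha = 0.05, cssi_max_iter = 10,
                                cell_threshold_mode = c("fixed", "otsu"),
                                medium_ri = 1.334, medium_margin = 0.004,
                                cssi_refine_band = 0.9,
                                min_component_voxels = 27) {
  if (lvc_quantile <= 0 || lvc_quantile >= 1)
    stop("lvc_quantile must lie strictly between 0 and 1", call. = FALSE)
  if (cssi_cube_side < 3)
    stop("cssi_cube_side must be >= 3 voxels", call. = FALSE)
  if (cssi_alpha <= 0 || cssi_alpha >= 1)
    stop("cssi_alpha must lie strictly between 0 and 1", call. = FALSE)
  structure(list(lvc_quantile = lvc_quantile,
                 cssi_cube_side = as.integer(cssi_cube_side),
                 cssi_alpha = cssi_alpha,
                 cssi_max_iter = as.integer(cssi_max_iter),
                 cell_threshold_mode = match.arg(cell_threshold_mode),
                 medium_ri = medium_ri, medium_margin = medium_margin,
                 cssi_refine_band = cssi_refine_band,
                 min_component_voxels = as.integer(min_component_voxels)),
            class = "segmentation_config")
}

#' Segment the cell body
#'
#' Thresholds the tomogram (fixed medium level + margin, or Otsu), removes
#' speckle with one 6-connected morphological opening (noise just above the
#' medium level otherwise percolates into the cell component), keeps the
#' largest 26-connected component, fills internal cavities and applies one
#' closing step (which also restores the boundary layer taken by the
#' opening).
#'
#' @param tomogram an [ri_tomogram()].
#' @param config a [segmentation_config()].
#' @return logical cell mask.
#' @export
segment_cell <- function(tomogram, config = segmentation_config()) {
  stopifnot(inherits(tomogram, "ri_tomogram"))
  v <- tomogram$values
  thr <- if (config$cell_threshold_mode == "fixed") {
    config$medium_ri + config$medium_margin
  } else {
    otsu_threshold(v)
  }
  fg <- v > thr
  if (!any(fg)) stop("no cell found: no voxels above the foreground threshold",
                     call. = FALSE)
  fg <- dilate3d(erode3d(fg, connectivity = 6, iter = 1),
                 connectivity = 6, iter = 1)
  if (!any(fg)) stop("no cell found: foreground vanishes under opening",
                     call. = FALSE)
  m <- largest_component(fg, connectivity = 26)
  m <- fill_holes(m)
  m <- close3d(m, connectivity = 6, iter = 1)
  # reclaim above-threshold boundary voxels the opening removed
  m <- m | ((v > thr) & dilate3d(m, connectivity = 6, iter = 1))
  fill_holes(m)
}

# standard between-class-variance threshold on a 256-bin histogram
otsu_threshold <- function(v) {
  r <- range(v)
  if (diff(r) == 0) return(r[1])
  breaks <- seq(r[1], r[2], length.out = 257)
  h <- tabulate(findInterval(v, breaks, all.inside = TRUE), nbins = 256)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Rough lysosomal volume by adaptive per-cell quantile thresholding
#'
#' Selects cellular voxels whose RI strictly exceeds the `lvc_quantile`
#' quantile of the RI distribution restricted to this cell's voxels. The
#' threshold is always per-cell, never shared across cells, so it adapts to
#' inter-cell RI variability.
#'
#' @inheritParams segment_cell
#' @param cell_mask logical cell mask (nonempty).
#' @return list with `mask` (logical rough-LVC mask) and `threshold` (the RI
#'   cutoff actually used).
#' @export
rough_lvc <- function(tomogram, cell_mask, config = segmentation_config()) {
  stopifnot(inherits(tomogram, "ri_tomogram"))
  check_mask3d(cell_mask)
  if (!any(cell_mask)) stop("cell mask is empty", call. = FALSE)
  ri_cell <- tomogram$values[cell_mask]
  thr <- as.numeric(quantile(ri_cell, config$lvc_quantile))
  list(mask = cell_mask & (tomogram$values > thr), threshold = thr)
}

# partition the grid into non-overlapping eps-cubes; returns the cube-grid
# dims and helpers mapping cube index -> voxel index ranges. Remainder voxels
# beyond the last full cube are not assigned to any cube.
cube_grid <- function(dim3, eps) {
  nc <- dim3 %/% eps
  if (any(nc < 1)) stop("epsilon-cube side exceeds the volume", call. = FALSE)
  list(nc = nc, eps = eps)
}

cube_voxel_ranges <- function(grid, cube_idx) {
  lapply(1:3, function(a) ((cube_idx[a] - 1L) * grid$eps + 1L):(cube_idx[a] * grid$eps))
}

#' Select the CSSI reference cube
#'
#' Among all epsilon-cubes fully inside the cell mask and containing no
#' rough-LVC voxels, returns the one whose centre is closest (Euclidean,
#' physical um) to the cell-mask centroid; ties broken by lowest (z, y, x)
#' cube index. The central cube is the natural nucleus seed in a suspended
#' quasi-spherical cell.
#'
#' @inheritParams rough_lvc
#' @param rough_lvc_mask logical rough-LVC mask.
#' @return integer length-3 cube index (z, y, x) with attribute
#'   `"voxel_ranges"`.
#' @export
select_reference_cube <- function(tomogram, cell_mask, rough_lvc_mask,
                                  config = segmentation_config()) {
  eps <- config$cssi_cube_side
  d <- dim(cell_mask)
  grid <- cube_grid(d, eps)
  vs <- tomogram$voxel_size
  ctr <- mask_centroid(cell_mask, vs) # x, y, z um

  # per-cube counts via block reduction
  nin <- block_sum(cell_mask, eps)
  nlvc <- block_sum(rough_lvc_mask, eps)
  admissible <- nin == eps^3 & nlvc == 0L
  if (!any(admissible))
    stop("no admissible reference cube (fully cellular, LVC-free); ",
         "try a smaller cssi_cube_side", call. = FALSE)
  idx <- which(admissible, arr.ind = TRUE) # (z, y, x) cube indices
  cx <- ((idx[, 3] - 0.5) * eps) * vs[3]
  cy <- ((idx[, 2] - 0.5) * eps) * vs[2]
  cz <- ((idx[, 1] - 0.5) * eps) * vs[1]
  dist2 <- (cx - ctr[1])^2 + (cy - ctr[2])^2 + (cz - ctr[3])^2
  ord <- order(dist2, idx[, 1], idx[, 2], idx[, 3])
  best <- as.integer(idx[ord[1], ])
  attr(best, "voxel_ranges") <- cube_voxel_ranges(grid, best)
  best
}

# sum of a logical/numeric array over non-overlapping eps-cubes ->
# array of dim floor(d / eps)
block_sum <- function(x, eps) {
  d <- dim(x)
  nc <- d %/% eps
  xt <- x[seq_len(nc[1] * eps), seq_len(nc[2] * eps), seq_len(nc[3] * eps),
          drop = FALSE]
  dim(xt) <- c(eps, nc[1], eps, nc[2], eps, nc[3])
  apply(xt, c(2, 4, 6), sum)
}

#' CSSI nucleus segmentation
#'
#' Statistical-inference region growing over epsilon-cubes: starting from the
#' reference cube, 6-connected candidate cubes join the region when the
#' two-sample Kolmogorov-Smirnov test cannot distinguish their in-cell RI
#' sample from the reference sample (p >= alpha). After each pass the
#' reference sample is re-pooled from the accepted region (deterministically
#' subsampled to at most `10 * eps^3` values) and the growth is repeated
#' until the accepted set is stable or `cssi_max_iter` passes. The accepted
#' voxel union is post-processed: restricted to the cell, largest connected
#' component containing the reference cube, hole filling, one closing step.
#'
#' @inheritParams select_reference_cube
#' @param ref_cube reference cube index from [select_reference_cube()].
#' @return logical nucleus mask with attribute `"cssi"` (list: iterations,
#'   accepted cube count, flags).
#' @export
cssi_nucleus <- function(tomogram, cell_mask, rough_lvc_mask, ref_cube,
                         config = segmentation_config()) {
  eps <- config$cssi_cube_side
  d <- dim(cell_mask)
  grid <- cube_grid(d, eps)
  nc <- grid$nc
  v <- tomogram$values

  nin <- block_sum(cell_mask, eps)
  candidate <- nin >= eps^3 / 2 # cubes at least half inside the cell
  ref_lin <- ref_cube[1] + nc[1] * (ref_cube[2] - 1L + nc[2] * (ref_cube[3] - 1L))
  if (!candidate[ref_lin]) stop("reference cube is not a candidate cube",
                                call. = FALSE)

  # in-cell RI sample per candidate cube
  cube_sample <- function(lin) {
    ci <- lin_to_cube(lin, nc)
    rg <- cube_voxel_ranges(grid, ci)
    vals <- v[rg[[1]], rg[[2]], rg[[3]]]
    vals[cell_mask[rg[[1]], rg[[2]], rg[[3]]]]
  }

  ref_sample <- cube_sample(ref_lin)
  accepted_prev <- integer(0)
  accepted <- ref_lin
  iterations <- 0L
  flags <- character()
  neighbours <- cube_neighbours(nc)

  while (iterations < config$cssi_max_iter &&
         !identical(sort(accepted), sort(accepted_prev))) {
    iterations <- iterations + 1L
    accepted_prev <- accepted
    # breadth-first growth from the reference cube with the current reference
    accepted <- ref_lin
    tested <- logical(prod(nc))
    tested[ref_lin] <- TRUE
    frontier <- ref_lin
    while (length(frontier)) {
      nbrs <- unique(unlist(neighbours[frontier]))
      nbrs <- nbrs[!tested[nbrs] & candidate[nbrs]]
      tested[nbrs] <- TRUE
      frontier <- integer(0)
      for (lin in nbrs) {
        smp <- cube_sample(lin)
        if (length(smp) < 5L) next
        p <- suppressWarnings(ks.test(smp, ref_sample)$p.value)
        if (is.finite(p) && p >= config$cssi_alpha) {
          accepted <- c(accepted, lin)
          frontier <- c(frontier, lin)
        }
      }
    }
    # re-pool the reference sample from the accepted region
    pooled <- sort(unlist(lapply(accepted, cube_sample)))
    cap <- 10L * eps^3
    if (length(pooled) > cap)
      pooled <- pooled[round(seq(1, length(pooled), length.out = cap))]
    ref_sample <- pooled
  }

  if (length(accepted) <= 1L) {
    warning("CSSI acceptance region is empty beyond the reference cube; ",
            "returning the reference cube only")
    flags <- c(flags, "degenerate_reference_only")
  }

  mask <- array(FALSE, d)
  for (lin in accepted) {
    rg <- cube_voxel_ranges(grid, lin_to_cube(lin, nc))
    mask[rg[[1]], rg[[2]], rg[[3]]] <- TRUE
  }
  mask <- mask & cell_mask

  # voxel-level boundary recovery: only cubes entirely inside the nucleus
  # pass the KS test, so the cube union underestimates the boundary by up to
  # a cube diagonal. Grow the region by 6-connected steps into cellular
  # voxels whose RI lies in the central `cssi_refine_band` of the reference
  # sample, for at most eps steps.
  band_half <- (1 - config$cssi_refine_band) / 2
  band <- quantile(ref_sample, c(band_half, 1 - band_half), names = FALSE)
  eligible <- cell_mask & !rough_lvc_mask & v >= band[1] & v <= band[2]
  for (it in seq_len(eps)) {
    grown <- (dilate3d(mask, connectivity = 6, iter = 1) & eligible) | mask
    if (identical(grown, mask)) break
    mask <- grown
  }

  lab <- label_components(mask, connectivity = 6)
  ref_rg <- cube_voxel_ranges(grid, ref_cube)
  ref_labels <- lab[ref_rg[[1]], ref_rg[[2]], ref_rg[[3]]]
  ref_label <- ref_labels[ref_labels > 0][1]
  mask <- array(lab == ref_label, d)
  mask <- fill_holes(mask)
  mask <- close3d(mask, connectivity = 6, iter = 1) & cell_mask

  if (sum(mask) > 0.7 * sum(cell_mask))
    flags <- c(flags, "nucleus_floods_cell") # no-contrast failure mode

  attr(mask, "cssi") <- list(iterations = iterations,
                             accepted_cubes = length(accepted),
                             flags = flags)
  mask
}

lin_to_cube <- function(lin, nc) {
  lin0 <- lin - 1L
  c(lin0 %% nc[1], (lin0 %/% nc[1]) %% nc[2], lin0 %/% (nc[1] * nc[2])) + 1L
}

# adjacency lists of the 6-connected cube grid, as linear indices
cube_neighbours <- function(nc) {
  n <- prod(nc)
  idx <- seq_len(n)
  iz <- (idx - 1L) %% nc[1] + 1L
  iy <- ((idx - 1L) %/% nc[1]) %% nc[2] + 1L
  ix <- (idx - 1L) %/% (nc[1] * nc[2]) + 1L
  res <- vector("list", n)
  for (i in idx) {
    nb <- integer(0)
    if (iz[i] > 1L) nb <- c(nb, i - 1L)
    if (iz[i] < nc[1]) nb <- c(nb, i + 1L)
    if (iy[i] > 1L) nb <- c(nb, i - nc[1])
    if (iy[i] < nc[2]) nb <- c(nb, i + nc[1])
    if (ix[i] > 1L) nb <- c(nb, i - nc[1] * nc[2])
    if (ix[i] < nc[3]) nb <- c(nb, i + nc[1] * nc[2])
    res[[i]] <- nb
  }
  res
}

#' Refine the rough lysosomal volume
#'
#' Deletes all rough-LVC voxels inside the nucleus (the adaptive RI threshold
#' can also capture the brightest nuclear voxels) and removes connected
#' components smaller than `min_component_voxels`.
#'
#' @param rough_lvc_mask,nucleus_mask logical masks of identical shape.
#' @param config a [segmentation_config()].
#' @return logical LVC mask with attribute `"flags"`.
#' @export
refine_lvc <- function(rough_lvc_mask, nucleus_mask,
                       config = segmentation_config()) {
  check_mask3d(rough_lvc_mask); check_mask3d(nucleus_mask)
  if (!identical(dim(rough_lvc_mask), dim(nucleus_mask)))
    stop("masks must share one shape", call. = FALSE)
  m <- rough_lvc_mask & !nucleus_mask
  flags <- character()
  if (any(m) && config$min_component_voxels > 1L) {
    lab <- label_components(m, connectivity = 6)
    counts <- tabulate(lab)
    keep <- which(counts >= config$min_component_voxels)
    m <- array(lab %in% keep, dim(m))
  }
  if (!any(m)) flags <- c(flags, "empty_lvc")
  attr(m, "flags") <- flags
  m
}

#' Full three-stage segmentation of one tomogram
#'
#' Convenience wrapper: cell mask, rough LVC, reference-cube selection, CSSI
#' nucleus, LVC refinement. Returns [compartment_masks()] plus provenance.
#'
#' @inheritParams segment_cell
#' @return a [compartment_masks()] whose `flags` aggregate stage flags, with
#'   attribute `"provenance"` (list: lvc_threshold, reference_cube,
#'   cssi_iterations).
#' @export
segment_tomogram <- function(tomogram, config = segmentation_config()) {
  cell <- segment_cell(tomogram, config)
  rl <- rough_lvc(tomogram, cell, config)
  ref <- select_reference_cube(tomogram, cell, rl$mask, config)
  nucleus <- cssi_nucleus(tomogram, cell, rl$mask, ref, config)
  cssi_info <- attr(nucleus, "cssi")
  lvc <- refine_lvc(rl$mask, nucleus, config)
  flags <- c(cssi_info$flags, attr(lvc, "flags"))
  attr(nucleus, "cssi") <- NULL
  attr(lvc, "flags") <- NULL
  # nucleus closing may touch voxels claimed by the refined LVC: nucleus wins
  # (refinement deletes intra-nuclear lysosomal voxels by definition)
  lvc <- lvc & !nucleus
  masks <- compartment_masks(cell, nucleus, lvc, tomogram$voxel_size,
                             flags = flags)
  attr(masks, "provenance") <- list(
    lvc_threshold = rl$threshold,
    reference_cube = as.integer(ref),
    cssi_iterations = cssi_info$iterations,
    accepted_cubes = cssi_info$accepted_cubes
  )
  masks
}
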