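#' Specification of a synthetic single-cell RI phantom
#'
#' Describes a quasi-spherical suspended cell in medium: an ellipsoidal cell
#' body (cytoplasm), a quasi-spherical nucleus, and high-RI lysosomal blobs
#' whose angular placement around a random pole axis is controlled by a
#' von-Mises-Fisher-style concentration `kappa` (0 = isotropic, wild-type-
#' like; large = one-pole accumulation, NPC-like). In the polarized
#' phenotype the nucleus is additionally displaced opposite the lysosomal
#' pole and flattened along it.
#'
#' @param grid_shape voxels per axis (scalar or z/y/x vector). Default 128.
#' @param voxel_size voxel edge in um (isotropic scalar or z/y/x). Default 0.15.
#' @param cell_radius nominal cell radius in um. Default 7.5.
#' @param cell_axis_jitter relative half-range of per-axis radius jitter
#'   (axis ratios drawn uniformly in `1 +/- jitter`). Default 0.05.
#' @param nucleus_radius nucleus radius in um. Default 3.5.
#' @param n_lysosome_blobs number of lysosomal blobs. Default 60.
#' @param blob_radius mean blob radius in um (jittered uniformly by
#'   `blob_radius_jitter`). Default 0.4.
#' @param blob_radius_jitter relative half-range of blob radius jitter.
#'   Default 0.3.
#' @param kappa concentration of blob directions about the pole axis
#'   (>= 0; clamped at 50). Default 0.
#' @param nucleus_offset_frac nucleus displacement opposite the pole, as a
#'   fraction of `cell_radius`. Default 0.
#' @param nucleus_flatten nucleus axis scale along the pole axis. Default 1.
#' @param lysosome_mode `"blobs"` (default) or `"shell"`: a complete
#'   concentric spherical shell around the nucleus (used for analytic
#'   solid-angle cases).
#' @param shell_radius_frac shell mid-radius as a fraction of `cell_radius`
#'   (shell mode). Default 0.7.
#' @param shell_thickness shell thickness in um (shell mode). Default 0.8.
#' @param ri_medium,ri_cytoplasm,ri_nucleus,ri_lysosome compartment RI
#'   levels. Defaults 1.334 / 1.355 / 1.345 / 1.395 (literature-typical for
#'   HeLa-like cells; the ordering lysosome > cytoplasm > nucleus > medium is
#'   enforced so lysosomes are the highest-RI structures).
#' @param noise_sd i.i.d. Gaussian noise, RI units. Default 0.004.
#' @param seed integer RNG seed. Default 1.
#' @return an object of class `phantom_spec` (a validated list).
#' @export
phantom_spec <- function(grid_shape = 128, voxel_size = 0.15,
                         cell_radius = 7.5, cell_axis_jitter = 0.05,
                         nucleus_radius = 3.5,
                         n_lysosome_blobs = 60, blob_radius = 0.4,
                         blob_radius_jitter = 0.3,
                         kappa = 0, nucleus_offset_frac = 0,
                         nucleus_flatten = 1,
                         lysosome_mode = c("blobs", "shell"),
                         shell_radius_frac = 0.7, shell_thickness = 0.8,
                         ri_medium = 1.334, ri_cytoplasm = 1.355,
                         ri_nucleus = 1.345, ri_lysosome = 1.395,
                         noise_sd = 0.004, seed = 1) {
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  grid_shape <- as.integer(grid_shape)
  voxel_size <- check_voxel_size(voxel_size)
  lysosome_mode <- match.arg(lysosome_mode)
  spec <- list(grid_shape = grid_shape, voxel_size = voxel_size,
               cell_radius = cell_radius, cell_axis_jitter = cell_axis_jitter,
               nucleus_radius = nucleus_radius,
               n_lysosome_blobs = as.integer(n_lysosome_blobs),
               blob_radius = blob_radius,
               blob_radius_jitter = blob_radius_jitter,
               kappa = min(kappa, 50), nucleus_offset_frac = nucleus_offset_frac,
               nucleus_flatten = nucleus_flatten,
               lysosome_mode = lysosome_mode,
               shell_radius_frac = shell_radius_frac,
               shell_thickness = shell_thickness,
               ri_medium = ri_medium, ri_cytoplasm = ri_cytoplasm,
               ri_nucleus = ri_nucleus, ri_lysosome = ri_lysosome,
               noise_sd = noise_sd, seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (nucleus_radius >= cell_radius)
      stop("nucleus_radius must be smaller than cell_radius", call. = FALSE)
    if (kappa < 0) stop("kappa must be >= 0", call. = FALSE)
    if (!(ri_lysosome > ri_cytoplasm && ri_cytoplasm > ri_nucleus &&
          ri_nucleus > ri_medium))
      stop("RI ordering must satisfy lysosome > cytoplasm > nucleus > medium",
           call. = FALSE)
    if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
    half_extent <- grid_shape * voxel_size / 2
    max_r <- cell_radius * (1 + cell_axis_jitter)
    if (any(max_r + 2 * voxel_size > half_extent))
      stop("cell (radius ", signif(max_r, 3),
           " um incl. jitter) does not fit in the grid with a 2-voxel margin",
           call. = FALSE)
  })
  invisible(spec)
}

#' Phenotype presets for the phantom generator
#'
#' `wt_like_spec()`: isotropic lysosome placement (kappa = 0), concentric
#' spherical nucleus. `ko_like_spec()`: one-pole lysosomal accumulation
#' (kappa = 8) with the nucleus displaced opposite the pole
#' (`nucleus_offset_frac = 0.3`) and flattened along it
#' (`nucleus_flatten = 0.75`), emulating the NPC-like phenotype.
#'
#' @param ... overrides forwarded to [phantom_spec()]; overrides may also
#'   replace the preset's own fields.
#' @return a `phantom_spec`.
#' @export
wt_like_spec <- function(...) {
  args <- utils::modifyList(
    list(kappa = 0, nucleus_offset_frac = 0, nucleus_flatten = 1), list(...))
  do.call(phantom_spec, args)
}

#' @rdname wt_like_spec
#' @export
ko_like_spec <- function(...) {
  args <- utils::modifyList(
    list(kappa = 8, nucleus_offset_frac = 0.3, nucleus_flatten = 0.75),
    list(...))
  do.call(phantom_spec, args)
}

# sample n unit vectors from a von-Mises-Fisher-style distribution about mu
sample_vmf <- function(n, mu, kappa) {
  if (kappa <= 0) {
    w <- runif(n, -1, 1)
  } else {
    u <- runif(n)
    # inverse-CDF of the vMF cosine on S^2: density prop. to exp(kappa * w)
    w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  }
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  # orthonormal basis (e1, e2, mu)
  ref <- if (abs(mu[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * mu) * mu
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(mu[2] * e1[3] - mu[3] * e1[2],
          mu[3] * e1[1] - mu[1] * e1[3],
          mu[1] * e1[2] - mu[2] * e1[1])
  t(vapply(seq_len(n), function(i)
    s[i] * cos(phi[i]) * e1 + s[i] * sin(phi[i]) * e2 + w[i] * mu,
    numeric(3)))
}

#' Generate one synthetic RI tomogram with ground truth
#'
#' Rasterizes the geometry described by a [phantom_spec()] onto the voxel
#' grid, assigns compartment RI levels, adds i.i.d. Gaussian noise, and
#' returns both the tomogram and the exact generative masks. Identical seeds
#' give bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `tomogram` ([ri_tomogram()]) and `truth`
#'   (class `phantom_truth`: `masks` ([compartment_masks()]), `pole_axis`,
#'   `blob_centers` (um, one row per blob), `blob_directions`, `spec`).
#' @export
generate_cell <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  set.seed(spec$seed)
  d <- spec$grid_shape
  vs <- spec$voxel_size
  center <- d * vs / 2 # physical (z, y, x) -> careful: store as x, y, z
  center_xyz <- c(center[3], center[2], center[1])

  # physical coordinate fields, arrays of dim (nz, ny, nx)
  zc <- ((seq_len(d[1]) - 0.5) * vs[1])
  yc <- ((seq_len(d[2]) - 0.5) * vs[2])
  xc <- ((seq_len(d[3]) - 0.5) * vs[3])
  Z <- array(rep(zc, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(yc, each = d[1]), times = d[3]), dim = d)
  X <- array(rep(xc, each = d[1] * d[2]), dim = d)

  ax <- spec$cell_radius *
    (1 + runif(3, -spec$cell_axis_jitter, spec$cell_axis_jitter)) # x, y, z radii
  pole <- sample_vmf(1, c(0, 0, 1), 0)[1, ] # random pole axis (x, y, z)

  cell <- ((X - center_xyz[1]) / ax[1])^2 + ((Y - center_xyz[2]) / ax[2])^2 +
    ((Z - center_xyz[3]) / ax[3])^2 <= 1

  nuc_center <- center_xyz - spec$nucleus_offset_frac * spec$cell_radius * pole
  dx <- X - nuc_center[1]; dy <- Y - nuc_center[2]; dz <- Z - nuc_center[3]
  tpar <- dx * pole[1] + dy * pole[2] + dz * pole[3]
  perp2 <- pmax(0, dx^2 + dy^2 + dz^2 - tpar^2)
  Rn <- spec$nucleus_radius
  nucleus <- (tpar / (Rn * spec$nucleus_flatten))^2 + perp2 / Rn^2 <= 1
  nucleus <- nucleus & cell

  lvc <- array(FALSE, d)
  blob_centers <- matrix(numeric(0), ncol = 3)
  blob_dirs <- matrix(numeric(0), ncol = 3)
  if (spec$lysosome_mode == "shell") {
    r_mid <- spec$shell_radius_frac * spec$cell_radius
    half_t <- spec$shell_thickness / 2
    rr <- sqrt(dx^2 + dy^2 + dz^2)
    lvc <- rr >= (r_mid - half_t) & rr <= (r_mid + half_t)
  } else if (spec$n_lysosome_blobs > 0) {
    nb <- spec$n_lysosome_blobs
    blob_dirs <- sample_vmf(nb, pole, spec$kappa)
    br <- spec$blob_radius *
      (1 + runif(nb, -spec$blob_radius_jitter, spec$blob_radius_jitter))
    r_lo <- spec$nucleus_radius + br
    r_hi <- 0.9 * min(ax) - br
    r_blob <- runif(nb, pmin(r_lo, r_hi), pmax(r_lo, r_hi))
    blob_centers <- sweep(blob_dirs * r_blob, 2, center_xyz, "+")
    for (b in seq_len(nb)) {
      # rasterize each blob only inside its bounding box
      c_b <- blob_centers[b, ] # x, y, z
      lo <- pmax(1L, floor(c(
        (c_b[3] - br[b]) / vs[1], (c_b[2] - br[b]) / vs[2],
        (c_b[1] - br[b]) / vs[3])) + 0L)
      hi <- pmin(d, ceiling(c(
        (c_b[3] + br[b]) / vs[1], (c_b[2] + br[b]) / vs[2],
        (c_b[1] + br[b]) / vs[3])) + 1L)
      if (any(lo > hi)) next
      iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
      sub <- outer(((iz - 0.5) * vs[1] - c_b[3])^2,
                   ((iy - 0.5) * vs[2] - c_b[2])^2, "+")
      sub <- outer(sub, ((ix - 0.5) * vs[3] - c_b[1])^2, "+")
      lvc[iz, iy, ix] <- lvc[iz, iy, ix] | (sub <= br[b]^2)
    }
  }
  # enforce compartment exclusivity: lysosomes live in the cytoplasm
  lvc <- lvc & cell & !nucleus

  vol <- array(spec$ri_medium, d)
  vol[cell] <- spec$ri_cytoplasm
  vol[nucleus] <- spec$ri_nucleus
  vol[lvc] <- spec$ri_lysosome
  if (spec$noise_sd > 0)
    vol <- vol + array(rnorm(prod(d), 0, spec$noise_sd), d)
  vol[vol < 1] <- 1 # physical floor; reachable only at extreme noise levels

  masks <- compartment_masks(cell, nucleus, lvc, vs)
  truth <- structure(list(masks = masks, pole_axis = pole,
                          blob_centers = blob_centers,
                          blob_directions = blob_dirs, spec = spec),
                     class = "phantom_truth")
  list(tomogram = ri_tomogram(vol, vs), truth = truth)
}

#' Generate a labelled population of phantoms
#'
#' Derives one RNG seed per cell deterministically from `master_seed`, applies
#' per-cell jitter to the nominal radii and concentration of each condition
#' preset, and generates all cells. The same `master_seed` always yields
#' byte-identical volumes.
#'
#' @param n_per_condition cells per condition (>= 1).
#' @param conditions named list of [phantom_spec()] presets.
#' @param master_seed integer seed controlling per-cell seeds and jitter.
#' @param radius_jitter relative half-range applied to cell and nucleus radii
#'   per cell. Default 0.08.
#' @param kappa_jitter relative half-range applied to kappa per cell.
#'   Default 0.5.
#' @param offset_jitter relative half-range applied to the nucleus
#'   displacement per cell. Default 0.5.
#' @param flatten_jitter relative half-range applied to the nucleus
#'   flattening per cell. Default 0.15.
#'
#' @details The default jitter half-ranges are deliberately wide: single-cell
#' morphometry distributions overlap heavily between phenotypes, and the
#' phantom population should reproduce that heterogeneity rather than two
#' point masses. Jitter is uniform and multiplicative, so a preset with a
#' zero-valued parameter (e.g. no nucleus displacement) stays exactly zero.
#' @return list of cells, each `list(tomogram, truth, condition, cell_id)`.
#' @export
generate_population <- function(n_per_condition, conditions, master_seed = 1,
                                radius_jitter = 0.08, kappa_jitter = 0.5,
                                offset_jitter = 0.5, flatten_jitter = 0.15) {
  if (n_per_condition < 1) stop("n_per_condition must be >= 1", call. = FALSE)
  if (is.null(names(conditions)) || any(!nzchar(names(conditions))))
    stop("conditions must be a named list of phantom_spec presets", call. = FALSE)
  n_total <- n_per_condition * length(conditions)
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  jit <- matrix(runif(5 * n_total, -1, 1), ncol = 5)
  cells <- vector("list", n_total)
  i <- 0L
  for (cond in names(conditions)) {
    base <- conditions[[cond]]
    stopifnot(inherits(base, "phantom_spec"))
    for (k in seq_len(n_per_condition)) {
      i <- i + 1L
      spec_i <- base
      spec_i$cell_radius <- base$cell_radius * (1 + radius_jitter * jit[i, 1])
      spec_i$nucleus_radius <- base$nucleus_radius * (1 + radius_jitter * jit[i, 2])
      spec_i$kappa <- max(0, base$kappa * (1 + kappa_jitter * jit[i, 3]))
      spec_i$nucleus_offset_frac <-
        base$nucleus_offset_frac * (1 + offset_jitter * jit[i, 4])
      spec_i$nucleus_flatten <-
        base$nucleus_flatten * (1 + flatten_jitter * jit[i, 5])
      spec_i$seed <- seeds[i]
      class(spec_i) <- "phantom_spec"
      validate_phantom_spec(spec_i)
      g <- generate_cell(spec_i)
      cells[[i]] <- list(tomogram = g$tomogram, truth = g$truth,
                         condition = cond,
                         cell_id = sprintf("%s_%03d", cond, k))
    }
  }
  cells
}
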