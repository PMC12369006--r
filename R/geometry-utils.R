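# Geometry helpers shared by the phantom, morphometry and segmentation code.
#
# Conventions (see the methods vignette):
#  * volumes are arrays with dim = c(nz, ny, nx); voxel_size is c(z, y, x) in um
#  * physical coordinates use the voxel-centre convention:
#      x = (k - 0.5) * vs_x, y = (j - 0.5) * vs_y, z = (i - 0.5) * vs_z
#    for 1-based array index (i, j, k); all geometry is computed in um.

# m x 3 matrix of (x, y, z) physical centres for TRUE voxels
voxel_coords <- function(mask, voxel_size) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(
    x = (idx[, 3] - 0.5) * voxel_size[3],
    y = (idx[, 2] - 0.5) * voxel_size[2],
    z = (idx[, 1] - 0.5) * voxel_size[1]
  )
}

mask_centroid <- function(mask, voxel_size) {
  pts <- voxel_coords(mask, voxel_size)
  if (nrow(pts) == 0L) return(c(x = NA_real_, y = NA_real_, z = NA_real_))
  colMeans(pts)
}

mask_volume <- function(mask, voxel_size) {
  sum(mask) * prod(voxel_size)
}

# radius of the sphere with the same volume as the mask
equivalent_radius <- function(mask, voxel_size) {
  (3 * mask_volume(mask, voxel_size) / (4 * pi))^(1 / 3)
}

# (azimuth, elevation, r) of points (m x 3, columns x/y/z) about an origin
to_spherical <- function(points, origin) {
  d <- sweep(points, 2, origin, "-")
  r <- sqrt(rowSums(d^2))
  az <- atan2(d[, 2], d[, 1])
  el <- asin(pmin(1, pmax(-1, ifelse(r > 0, d[, 3] / r, 0))))
  cbind(azimuth = az, elevation = el, r = r)
}

#' Equal-area direction partition of the unit sphere
#'
#' Builds a subdivided-icosahedron partition with `20 * f^2` approximately
#' equal-area triangular cells and returns the unit direction at each cell
#' centre. Directions are assigned to cells by nearest centre (spherical
#' Voronoi of the cell centres), which is how the normalized solid-angle
#' coverage statistic discretizes the sphere.
#'
#' @param n_directions number of cells; must be `20 * f^2` for integer `f`
#'   (e.g. 80, 320, 1280, 5120). Default 1280.
#' @return numeric matrix `n_directions x 3` of unit vectors.
#' @export
icosphere_directions <- function(n_directions = 1280) {
  f <- sqrt(n_directions / 20)
  if (abs(f - round(f)) > 1e-9 || f < 1)
    stop("n_directions must be 20 * f^2 for a positive integer f", call. = FALSE)
  f <- as.integer(round(f))
  key <- as.character(n_directions)
  cached <- .icosphere_cache[[key]]
  if (!is.null(cached)) return(cached)

  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  faces <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  centers <- matrix(0, nrow = 20 * f^2, ncol = 3)
  row <- 1L
  for (fi in seq_len(nrow(faces))) {
    v1 <- v[faces[fi, 1], ]; v2 <- v[faces[fi, 2], ]; v3 <- v[faces[fi, 3], ]
    for (i in 0:(f - 1)) {
      for (j in 0:(f - 1 - i)) {
        # upward sub-triangle (i, j), (i+1, j), (i, j+1) in barycentric steps
        p1 <- (v1 * (f - i - j) + v2 * i + v3 * j) / f
        p2 <- (v1 * (f - i - 1 - j) + v2 * (i + 1) + v3 * j) / f
        p3 <- (v1 * (f - i - j - 1) + v2 * i + v3 * (j + 1)) / f
        centers[row, ] <- p1 + p2 + p3
        row <- row + 1L
        if (i + j <= f - 2) { # matching downward sub-triangle
          p4 <- (v1 * (f - i - 1 - j - 1) + v2 * (i + 1) + v3 * (j + 1)) / f
          centers[row, ] <- p2 + p3 + p4
          row <- row + 1L
        }
      }
    }
  }
  centers <- centers / sqrt(rowSums(centers^2))
  assign(key, centers, envir = .icosphere_cache)
  centers
}

.icosphere_cache <- new.env(parent = emptyenv())

# index of the nearest partition centre for each unit direction (chunked to
# bound memory at large voxel counts)
assign_direction_cells <- function(dirs, centers, chunk = 20000L) {
  m <- nrow(dirs)
  out <- integer(m)
  for (start in seq(1L, m, by = chunk)) {
    end <- min(start + chunk - 1L, m)
    sims <- dirs[start:end, , drop = FALSE] %*% t(centers)
    out[start:end] <- max.col(sims, ties.method = "first")
  }
  out
}

unit_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  keep <- n > 0
  m[keep, , drop = FALSE] / n[keep]
}
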