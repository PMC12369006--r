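# Independent oracles. Each one recomputes a quantity by a route that shares
# no code with the package implementation it checks.

# Monte-Carlo solid-angle oracle: cast random rays from the origin and march
# along each until it either hits an LVC voxel or leaves the radial range
# spanned by the LVC. Estimates the fraction of the sphere subtended by the
# LVC as seen from `origin` (um).
mc_solid_angle <- function(lvc_mask, voxel_size, origin, n_rays = 2e5,
                           seed = 42) {
  set.seed(seed)
  d <- dim(lvc_mask)
  idx <- which(lvc_mask, arr.ind = TRUE)
  px <- (idx[, 3] - 0.5) * voxel_size[3]
  py <- (idx[, 2] - 0.5) * voxel_size[2]
  pz <- (idx[, 1] - 0.5) * voxel_size[1]
  r_all <- sqrt((px - origin[1])^2 + (py - origin[2])^2 + (pz - origin[3])^2)
  r_min <- max(0, min(r_all) - max(voxel_size))
  r_max <- max(r_all) + max(voxel_size)
  # uniform directions via normalized Gaussians
  u <- matrix(rnorm(3 * n_rays), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  hit <- logical(n_rays)
  step <- 0.5 * min(voxel_size)
  for (r in seq(r_min, r_max, by = step)) {
    alive <- !hit
    if (!any(alive)) break
    pxr <- origin[1] + r * u[alive, 1]
    pyr <- origin[2] + r * u[alive, 2]
    pzr <- origin[3] + r * u[alive, 3]
    i <- ceiling(pzr / voxel_size[1])
    j <- ceiling(pyr / voxel_size[2])
    k <- ceiling(pxr / voxel_size[3])
    ok <- i >= 1 & j >= 1 & k >= 1 & i <= d[1] & j <= d[2] & k <= d[3]
    lin <- i[ok] + d[1] * (j[ok] - 1 + d[2] * (k[ok] - 1))
    h <- logical(sum(alive))
    h[ok] <- lvc_mask[lin]
    hit[alive] <- h
  }
  mean(hit)
}

# brute-force HLVR: explicit voxel enumeration and half-space count in a
# double loop over coordinates (no matrix algebra)
brute_hlvr <- function(masks) {
  vs <- masks$voxel_size
  nidx <- which(masks$nucleus, arr.ind = TRUE)
  cn <- c(mean((nidx[, 3] - 0.5) * vs[3]), mean((nidx[, 2] - 0.5) * vs[2]),
          mean((nidx[, 1] - 0.5) * vs[1]))
  lidx <- which(masks$lvc, arr.ind = TRUE)
  lx <- (lidx[, 3] - 0.5) * vs[3]
  ly <- (lidx[, 2] - 0.5) * vs[2]
  lz <- (lidx[, 1] - 0.5) * vs[1]
  cl <- c(mean(lx), mean(ly), mean(lz))
  nv <- cl - cn
  nv <- nv / sqrt(sum(nv^2))
  n_plus <- 0L
  for (v in seq_along(lx)) {
    if ((lx[v] - cn[1]) * nv[1] + (ly[v] - cn[2]) * nv[2] +
        (lz[v] - cn[3]) * nv[3] >= 0) n_plus <- n_plus + 1L
  }
  n_plus / length(lx)
}

# brute-force PSSE on explicit point lists, loop-built histograms
brute_psse <- function(points_a, points_b, origin, n_az = 36, n_el = 18) {
  sph <- function(p) {
    dx <- p[, 1] - origin[1]; dy <- p[, 2] - origin[2]; dz <- p[, 3] - origin[3]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    list(az = atan2(dy, dx), el = asin(pmin(1, pmax(-1, dz / r))))
  }
  a <- sph(points_a); b <- sph(points_b)
  count_bins <- function(x, breaks) {
    h <- numeric(length(breaks) - 1)
    for (v in x) {
      for (bb in seq_len(length(breaks) - 1)) {
        if (v >= breaks[bb] && (v < breaks[bb + 1] || bb == length(breaks) - 1)) {
          h[bb] <- h[bb] + 1
          break
        }
      }
    }
    h / sum(h)
  }
  az_breaks <- seq(-pi, pi, length.out = n_az + 1)
  el_breaks <- asin(seq(-1, 1, length.out = n_el + 1))
  p_az <- count_bins(a$az, az_breaks); q_az <- count_bins(b$az, az_breaks)
  p_el <- count_bins(a$el, el_breaks); q_el <- count_bins(b$el, el_breaks)
  psse_az <- 100 * sum((p_az - q_az)^2) / sum(q_az^2)
  psse_el <- 100 * sum((p_el - q_el)^2) / sum(q_el^2)
  c(az = psse_az, el = psse_el, azel = psse_az + psse_el)
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
# (feasible for n_a + n_b <= 16); midranks for ties, U statistic of group a
exact_mannwhitney <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u_stat <- function(sel) sum(rk[sel]) - n_a * (n_a + 1) / 2
  obs <- u_stat(seq_len(n_a))
  combs <- utils::combn(n_a + n_b, n_a)
  u_all <- apply(combs, 2, u_stat)
  mu <- n_a * n_b / 2
  # two-sided: as extreme or more extreme on either side
  p <- mean(abs(u_all - mu) >= abs(obs - mu) - 1e-12)
  list(u = obs, p = p)
}
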