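# Desk-scale phantom presets shared across tests: 72^3 voxels at 0.15 um
# keeps every geometric ratio of the full-scale defaults (blob diameter
# ~5 voxels, nucleus ~27 voxels) while one cell generates in well under a
# second.

desk_scale <- list(grid_shape = 72, voxel_size = 0.15, cell_radius = 4.2,
                   nucleus_radius = 2.0, n_lysosome_blobs = 40,
                   blob_radius = 0.4)

desk_wt <- function(...) {
  do.call(wt_like_spec, utils::modifyList(desk_scale, list(...)))
}

desk_ko <- function(...) {
  do.call(ko_like_spec, utils::modifyList(desk_scale, list(...)))
}

desk_shell <- function(...) {
  phantom_spec(grid_shape = 72, voxel_size = 0.15, cell_radius = 4.2,
               nucleus_radius = 2.0, lysosome_mode = "shell",
               shell_radius_frac = 0.7, shell_thickness = 0.6,
               noise_sd = 0, ...)
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# box-shaped compartment masks for hand-constructed feature cases
box_masks <- function(dim3 = c(48, 48, 48), voxel_size = 0.2,
                      nucleus_range = list(22:26, 22:26, 22:26),
                      lvc_index = NULL) {
  cell <- array(TRUE, dim3)
  nucleus <- array(FALSE, dim3)
  nucleus[nucleus_range[[1]], nucleus_range[[2]], nucleus_range[[3]]] <- TRUE
  lvc <- array(FALSE, dim3)
  if (!is.null(lvc_index)) lvc[lvc_index] <- TRUE
  compartment_masks(cell, nucleus, lvc & !nucleus, voxel_size)
}
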