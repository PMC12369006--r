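#' 3D binary morphology helpers
#'
#' Thin wrappers over the compiled 3D primitives. All functions take and
#' return logical arrays with `dim = c(nz, ny, nx)`.
#'
#' @param mask logical 3D array.
#' @param connectivity 6 (face neighbours) or 26 (full neighbourhood).
#' @param iter number of elementary dilation/erosion steps.
#' @return `label_components()` returns an integer array of component labels
#'   (0 = background); the others return logical arrays.
#' @name morph3d
NULL

check_mask3d <- function(mask) {
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop("expected a logical 3D array", call. = FALSE)
  if (anyNA(mask)) stop("mask contains NA", call. = FALSE)
  invisible(mask)
}

#' @rdname morph3d
#' @export
label_components <- function(mask, connectivity = 6) {
  check_mask3d(mask)
  connectivity <- match.arg(as.character(connectivity), c("6", "26"))
  .cpp_label_components(mask, dim(mask), as.integer(connectivity))
}

#' @rdname morph3d
#' @export
largest_component <- function(mask, connectivity = 6) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask & FALSE)
  counts <- tabulate(lab)
  array(lab == which.max(counts), dim(mask))
}

#' @rdname morph3d
#' @export
fill_holes <- function(mask) {
  check_mask3d(mask)
  .cpp_fill_holes(mask, dim(mask))
}

#' @rdname morph3d
#' @export
dilate3d <- function(mask, connectivity = 6, iter = 1) {
  check_mask3d(mask)
  .cpp_dilate(mask, dim(mask), as.integer(connectivity), as.integer(iter))
}

#' @rdname morph3d
#' @export
erode3d <- function(mask, connectivity = 6, iter = 1) {
  check_mask3d(mask)
  .cpp_erode(mask, dim(mask), as.integer(connectivity), as.integer(iter))
}

#' @rdname morph3d
#' @export
close3d <- function(mask, connectivity = 6, iter = 1) {
  erode3d(dilate3d(mask, connectivity, iter), connectivity, iter)
}

# total exposed voxel-face count (units: faces; multiply by face area for um^2)
exposed_faces <- function(mask) {
  check_mask3d(mask)
  .cpp_exposed_faces(mask, dim(mask))
}
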