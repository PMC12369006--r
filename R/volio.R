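#' Refractive-index tomogram container
#'
#' Wraps a 3D scalar field of refractive-index (RI) values with its physical
#' voxel size. Arrays are stored with axis order `(z, y, x)`; `voxel_size` is
#' the per-axis voxel edge length in micrometres, in the same `(z, y, x)`
#' order (a scalar is recycled to an isotropic grid).
#'
#' @param values numeric 3D array of RI values (dimensionless, all >= 1).
#' @param voxel_size numeric scalar or length-3 vector, um per voxel.
#' @return an object of class `ri_tomogram` with elements `values` and
#'   `voxel_size`.
#' @export
ri_tomogram <- function(values, voxel_size) {
  if (length(dim(values)) != 3L)
    stop("tomogram values must be a 3D array", call. = FALSE)
  if (any(dim(values) < 16L))
    stop("each tomogram axis must have at least 16 voxels", call. = FALSE)
  if (!all(is.finite(values)))
    stop("tomogram contains non-finite values", call. = FALSE)
  if (min(values) < 1)
    stop("refractive-index values below 1.0 are not physical", call. = FALSE)
  voxel_size <- check_voxel_size(voxel_size)
  structure(list(values = values, voxel_size = voxel_size),
            class = "ri_tomogram")
}

check_voxel_size <- function(voxel_size) {
  if (is.null(voxel_size) || length(voxel_size) == 0L || anyNA(voxel_size))
    stop("voxel size is required (um); refusing to assume a default",
         call. = FALSE)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be a positive scalar or length-3 vector", call. = FALSE)
  as.numeric(voxel_size)
}

#' @export
print.ri_tomogram <- function(x, ...) {
  cat("<ri_tomogram> ", paste(dim(x$values), collapse = " x "),
      " voxels (z y x), voxel size ",
      paste(signif(x$voxel_size, 4), collapse = " x "), " um\n",
      "  RI range: ", paste(signif(range(x$values), 6), collapse = " .. "),
      "\n", sep = "")
  invisible(x)
}

#' Compartment masks for one cell
#'
#' Binary volumes for the cell body, the nucleus and the LVC (lysosomal
#' volumes' container), all on the tomogram grid. Invariants enforced:
#' nucleus and LVC are subsets of the cell, the nucleus and the LVC are
#' disjoint, and the cell mask is nonempty.
#'
#' @param cell,nucleus,lvc logical 3D arrays of identical shape.
#' @param voxel_size voxel edge length(s) in um (scalar or z/y/x vector).
#' @param flags optional character vector of quality flags (e.g. produced by
#'   the segmentation stage).
#' @return an object of class `compartment_masks`.
#' @export
compartment_masks <- function(cell, nucleus, lvc, voxel_size, flags = character()) {
  check_mask3d(cell); check_mask3d(nucleus); check_mask3d(lvc)
  d <- dim(cell)
  if (!identical(d, dim(nucleus)) || !identical(d, dim(lvc)))
    stop("cell, nucleus and lvc masks must share one shape", call. = FALSE)
  if (!any(cell)) stop("cell mask is empty", call. = FALSE)
  if (any(nucleus & !cell)) stop("nucleus mask extends outside the cell", call. = FALSE)
  if (any(lvc & !cell)) stop("lvc mask extends outside the cell", call. = FALSE)
  if (any(nucleus & lvc)) stop("nucleus and lvc masks overlap", call. = FALSE)
  if (!any(lvc)) flags <- union(flags, "empty_lvc")
  if (!any(nucleus)) flags <- union(flags, "empty_nucleus")
  structure(list(cell = cell, nucleus = nucleus, lvc = lvc,
                 voxel_size = check_voxel_size(voxel_size), flags = flags),
            class = "compartment_masks")
}

#' @export
print.compartment_masks <- function(x, ...) {
  cat("<compartment_masks> ", paste(dim(x$cell), collapse = " x "),
      " voxels; |cell| = ", sum(x$cell), ", |nucleus| = ", sum(x$nucleus),
      ", |lvc| = ", sum(x$lvc), "\n", sep = "")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# volume I/O

#' Read / write 3D volumes (multi-page TIFF or NRRD)
#'
#' `write_volume()` stores a tomogram either as an uncompressed multi-page
#' 32-bit-float TIFF (one page per z slice) or as a raw-encoded NRRD file
#' that also records the voxel spacings. `read_volume()` reverses either.
#' TIFF carries no voxel-size metadata, so reading a TIFF requires
#' `voxel_size`; NRRD propagates the spacings from its header.
#'
#' @param tomogram an [ri_tomogram()].
#' @param path file path; format is taken from `format`, or from the
#'   extension (`.tif`/`.tiff` vs `.nrrd`) when `format = "auto"`.
#' @param format `"auto"`, `"tiff"` or `"nrrd"`.
#' @param voxel_size voxel size in um, required for TIFF input; if supplied
#'   for NRRD it overrides the header spacings.
#' @return `read_volume()` returns an [ri_tomogram()].
#' @export
write_volume <- function(tomogram, path, format = c("auto", "tiff", "nrrd")) {
  stopifnot(inherits(tomogram, "ri_tomogram"))
  format <- resolve_format(match.arg(format), path)
  if (format == "tiff") {
    write_tiff_float32(tomogram$values, path)
  } else {
    write_nrrd(tomogram$values, path, type = "float",
               spacings = tomogram$voxel_size)
  }
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, format = c("auto", "tiff", "nrrd"),
                        voxel_size = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- resolve_format(match.arg(format), path)
  if (format == "tiff") {
    vals <- read_tiff_volume(path)
    if (is.null(voxel_size))
      stop("TIFF volumes carry no voxel size; pass voxel_size explicitly",
           call. = FALSE)
    ri_tomogram(vals, voxel_size)
  } else {
    nr <- read_nrrd(path)
    vs <- if (!is.null(voxel_size)) voxel_size else nr$spacings
    if (is.null(vs))
      stop("NRRD header has no spacings; pass voxel_size explicitly",
           call. = FALSE)
    ri_tomogram(nr$values, vs)
  }
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext == "nrrd") return("nrrd")
  stop("cannot infer format from extension '", ext,
       "'; pass format = \"tiff\" or \"nrrd\"", call. = FALSE)
}

# The tiff package reads float32 TIFFs faithfully but cannot *write* samples
# outside [0, 1] (RI values start at ~1.33), so the writer emits a minimal
# uncompressed little-endian TIFF itself: one strip per page, SampleFormat
# IEEE float. Verified readable by libtiff (tiff::readTIFF) and tifffile.
write_tiff_float32 <- function(values, path) {
  d <- dim(values) # (z, y, x)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(c(42L), con, size = 2, endian = "little")
  data_bytes <- 4L * nx * ny
  n_tags <- 10L
  ifd_bytes <- 2L + n_tags * 12L + 4L
  # layout: 8-byte header, then per page [pixel data][IFD]
  page_bytes <- data_bytes + ifd_bytes
  first_ifd <- 8L + data_bytes
  writeBin(as.integer(first_ifd), con, size = 4, endian = "little")
  tag <- function(id, type, count, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) { # SHORT padded to 4 bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (z in seq_len(nz)) {
    # page pixels, row-major (y rows of x samples)
    slab <- t(matrix(values[z, , ], nrow = ny, ncol = nx)) # x by y
    writeBin(as.vector(as.single(as.vector(slab))), con, size = 4,
             endian = "little")
    data_offset <- 8L + (z - 1L) * page_bytes
    next_ifd <- if (z < nz) data_offset + page_bytes + data_bytes else 0L
    writeBin(as.integer(n_tags), con, size = 2, endian = "little")
    tag(256, 4, 1, nx)            # ImageWidth
    tag(257, 4, 1, ny)            # ImageLength
    tag(258, 3, 1, 32)            # BitsPerSample
    tag(259, 3, 1, 1)             # Compression = none
    tag(262, 3, 1, 1)             # Photometric = BlackIsZero
    tag(273, 4, 1, data_offset)   # StripOffsets
    tag(277, 3, 1, 1)             # SamplesPerPixel
    tag(278, 4, 1, ny)            # RowsPerStrip
    tag(279, 4, 1, data_bytes)    # StripByteCounts
    tag(339, 3, 1, 3)             # SampleFormat = IEEE float
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
  }
  invisible(path)
}

read_tiff_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("expected single-channel 2D pages; input is not a 3D scalar volume",
         call. = FALSE)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  vals <- array(NA_real_, dim = c(length(pages), ny, nx))
  for (z in seq_along(pages)) vals[z, , ] <- pages[[z]]
  if (length(pages) < 2L)
    stop("TIFF has a single page; a 3D volume is required", call. = FALSE)
  vals
}

# ---------------------------------------------------------------------------
# minimal NRRD codec (raw encoding, little-endian); kept deliberately small:
# enough for float volumes and uint8 label volumes with spacings metadata.

write_nrrd <- function(values, path, type = c("float", "uint8"),
                       spacings = NULL) {
  type <- match.arg(type)
  d <- dim(values)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(rev(d), collapse = " ")), # fastest axis first
    "encoding: raw",
    "endian: little"
  )
  if (!is.null(spacings))
    hdr <- c(hdr, paste0("spacings: ", paste(rev(spacings), collapse = " ")))
  writeLines(c(hdr, ""), con)
  # NRRD fastest axis first = x; our arrays are (z, y, x) column-major, i.e.
  # z fastest, so permute to (x, y, z) before streaming
  v <- aperm(values, c(3, 2, 1))
  if (type == "float") {
    writeBin(as.vector(as.single(as.vector(v))), con, size = 4,
             endian = "little")
  } else {
    writeBin(as.raw(as.integer(v)), con)
  }
  invisible(path)
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD000", magic)) stop("not an NRRD file: ", path, call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0L || line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(kv[2])]] <- kv[3]
  }
  if (is.null(fields$dimension) || as.integer(fields$dimension) != 3L)
    stop("only 3-dimensional NRRD volumes are supported", call. = FALSE)
  sizes <- as.integer(strsplit(trimws(fields$sizes), "[ \t]+")[[1]])
  type <- fields$type
  if (is.null(fields$encoding) || fields$encoding != "raw")
    stop("only raw-encoded NRRD is supported", call. = FALSE)
  n <- prod(sizes)
  if (type %in% c("float", "float32")) {
    raw_vals <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  } else if (type %in% c("uchar", "uint8", "unsigned char")) {
    raw_vals <- as.integer(readBin(con, "raw", n = n))
  } else {
    stop("unsupported NRRD type: ", type, call. = FALSE)
  }
  vals <- aperm(array(raw_vals, dim = sizes), c(3, 2, 1)) # back to (z, y, x)
  spacings <- NULL
  if (!is.null(fields$spacings))
    spacings <- rev(as.numeric(strsplit(trimws(fields$spacings), "[ \t]+")[[1]]))
  list(values = vals, spacings = spacings)
}

# ---------------------------------------------------------------------------
# mask (label volume) I/O

#' Convert compartment masks to/from a label volume
#'
#' Label encoding: 0 = background, 1 = cytoplasm (cell outside nucleus and
#' LVC), 2 = nucleus, 3 = LVC. Decoding reconstructs the nested binary masks
#' (cell = labels {1, 2, 3}).
#'
#' @param masks a [compartment_masks()].
#' @param labels integer 3D array of labels in {0, 1, 2, 3}.
#' @param voxel_size voxel size in um.
#' @return `masks_to_labels()` an integer array; `labels_to_masks()` a
#'   [compartment_masks()].
#' @export
masks_to_labels <- function(masks) {
  stopifnot(inherits(masks, "compartment_masks"))
  lab <- array(0L, dim(masks$cell))
  lab[masks$cell] <- 1L
  lab[masks$nucleus] <- 2L
  lab[masks$lvc] <- 3L
  lab
}

#' @rdname masks_to_labels
#' @export
labels_to_masks <- function(labels, voxel_size) {
  if (length(dim(labels)) != 3L)
    stop("label volume must be 3D", call. = FALSE)
  bad <- setdiff(unique(as.vector(labels)), 0:3)
  if (length(bad))
    stop("unknown label value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  compartment_masks(cell = labels >= 1L, nucleus = labels == 2L,
                    lvc = labels == 3L, voxel_size = voxel_size)
}

#' Read / write compartment masks as 8-bit label volumes
#'
#' @inheritParams write_volume
#' @param masks a [compartment_masks()].
#' @param voxel_size required when reading TIFF labels (no metadata).
#' @export
write_masks <- function(masks, path, format = c("auto", "tiff", "nrrd")) {
  stopifnot(inherits(masks, "compartment_masks"))
  format <- resolve_format(match.arg(format), path)
  lab <- masks_to_labels(masks)
  if (format == "tiff") {
    pages <- lapply(seq_len(dim(lab)[1]), function(z)
      matrix(lab[z, , ] / 255, nrow = dim(lab)[2], ncol = dim(lab)[3]))
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else {
    write_nrrd(lab, path, type = "uint8", spacings = masks$voxel_size)
  }
  invisible(path)
}

#' @rdname write_masks
#' @export
read_masks <- function(path, format = c("auto", "tiff", "nrrd"),
                       voxel_size = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- resolve_format(match.arg(format), path)
  if (format == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    lab <- array(0L, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (z in seq_along(pages)) lab[z, , ] <- as.integer(round(pages[[z]] * 255))
    if (is.null(voxel_size))
      stop("TIFF label volumes carry no voxel size; pass voxel_size",
           call. = FALSE)
    labels_to_masks(lab, voxel_size)
  } else {
    nr <- read_nrrd(path)
    vs <- if (!is.null(voxel_size)) voxel_size else nr$spacings
    if (is.null(vs))
      stop("NRRD header has no spacings; pass voxel_size explicitly",
           call. = FALSE)
    labels_to_masks(nr$values, vs)
  }
}
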