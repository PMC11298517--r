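# Stack I/O contract: multipage (or per-slice directory) grayscale TIFF
# plus a JSON sidecar "<file>.json" carrying dtype, scale factor, shape,
# voxel size and acquisition metadata. Integer data are stored as 16-bit
# and round-trip bit-exactly; floating-point data are stored as 32-bit
# float scaled into [0,1] (the TIFF library leaves out-of-range float
# storage undefined) and round-trip within float32 precision.

sidecar_path <- function(path) paste0(path, ".json")

.meta_to_list <- function(m) {
  if (is.null(m)) return(NULL)
  unclass(m)
}

.meta_from_list <- function(l) {
  if (is.null(l) || length(l) == 0L) return(NULL)
  md <- acquisition_metadata(l$excitation_nm,
                             emission_filter = l$emission_filter,
                             exposure_ms = l$exposure_ms,
                             laser_power = l$laser_power,
                             voxel_size_um = unlist(l$voxel_size_um),
                             side = l$side)
  if (isTRUE(l$normalized)) md$normalized <- TRUE
  md
}

#' Write a single-channel stack to TIFF
#'
#' Writes a (z, y, x) array as a multipage grayscale TIFF with a JSON
#' sidecar holding voxel size and channel metadata. Integer arrays are
#' stored losslessly as 16-bit; floating-point arrays as 32-bit float
#' (scaled, scale recorded in the sidecar).
#'
#' @param x 3D array (z, y, x) or 2D matrix (single slice); finite,
#'   nonnegative values.
#' @param path output file path (`.tif`).
#' @param metadata optional [acquisition_metadata()] embedded in the
#'   sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path, metadata = NULL) {
  x <- as_stack3d(x)
  stopifnot_3d(x)
  if (any(!is.finite(x))) stop("array contains non-finite values", call. = FALSE)
  if (min(x) < 0) stop("array contains negative values; stacks store ",
                       "nonnegative intensities", call. = FALSE)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("destination directory does not exist: ", dir,
                             call. = FALSE)
  is_int <- is.integer(x) || identical(storage.mode(x), "integer")
  if (is_int) {
    if (max(x) > 65535L) stop("integer data exceed 16-bit range", call. = FALSE)
    dtype <- "uint16"; scale <- 65535
    pages <- lapply(seq_len(dim(x)[1]), function(z) x[z, , ] / 65535)
    bits <- 16L
  } else {
    dtype <- "float32"
    scale <- max(x)
    if (scale == 0) scale <- 1
    pages <- lapply(seq_len(dim(x)[1]), function(z) x[z, , ] / scale)
    bits <- 32L
  }
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = bits,
                            compression = "deflate", reduce = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("destination not writable: ", path, call. = FALSE)
  side <- list(dtype = dtype, scale = scale, shape = dim(x),
               metadata = .meta_to_list(metadata))
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

.read_tiff_pages <- function(path, as_is) {
  pages <- try(tiff::readTIFF(path, all = TRUE, as.is = as_is), silent = TRUE)
  if (inherits(pages, "try-error"))
    stop("unreadable TIFF: ", path, call. = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p[, , 1] else p  # collapse stray RGB planes
  })
}

#' Read a single-channel stack from TIFF
#'
#' Reads a multipage TIFF, an OME-style TIFF, or a directory of
#' per-slice TIFFs (ordered by filename) into a (z, y, x) array.
#' Integer pixel types are preserved on read. If a JSON sidecar written
#' by [write_stack()] is present, its voxel size overrides the supplied
#' config metadata, with a notice.
#'
#' @param path TIFF file or directory of slice TIFFs.
#' @param metadata optional [acquisition_metadata()] from a channel
#'   config; overridden by sidecar metadata when both carry voxel size.
#' @return 3D array with attribute `"metadata"` (an
#'   `acquisition_metadata` or `NULL`).
#' @export
read_stack <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  side <- NULL
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) == 0L) stop("no TIFF slices found in ", path, call. = FALSE)
    if (file.exists(sidecar_path(files[1])))
      side <- jsonlite::read_json(sidecar_path(files[1]), simplifyVector = TRUE)
    as_is <- is.null(side) || identical(side$dtype, "uint16")
    pages <- unlist(lapply(files, .read_tiff_pages, as_is = as_is),
                    recursive = FALSE)
  } else {
    if (file.exists(sidecar_path(path)))
      side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    as_is <- is.null(side) || identical(side$dtype, "uint16")
    pages <- .read_tiff_pages(path, as_is = as_is)
  }
  shp <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1))))
    stop("inconsistent slice shapes across TIFF pages", call. = FALSE)
  x <- array(0, dim = c(length(pages), shp))
  for (z in seq_along(pages)) x[z, , ] <- pages[[z]]
  if (!is.null(side)) {
    if (identical(side$dtype, "uint16")) {
      storage.mode(x) <- "integer"
    } else {
      x <- x * side$scale
    }
    smeta <- .meta_from_list(side$metadata)
    if (!is.null(smeta)) {
      if (!is.null(metadata) &&
          !isTRUE(all.equal(metadata$voxel_size_um, smeta$voxel_size_um)))
        message("voxel size from stack sidecar (",
                paste(smeta$voxel_size_um, collapse = "x"),
                " um) overrides channel config (",
                paste(metadata$voxel_size_um, collapse = "x"), " um)")
      metadata <- smeta
    }
  } else if (as_is && !any(x != floor(x))) {
    storage.mode(x) <- "integer"
  }
  attr(x, "metadata") <- metadata
  x
}

#' Write a region label volume to TIFF
#'
#' Labels are stored as a 16-bit integer stack; the class-name map goes
#' into the JSON sidecar.
#'
#' @param x a [region_label_volume()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(x, path) {
  stopifnot(inherits(x, "region_label_volume"))
  write_stack(x$labels, path)
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  side$class_names <- as.list(x$class_names)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a region label volume from TIFF
#'
#' @param path label TIFF written by [write_labels()], or any integer
#'   TIFF stack.
#' @param class_names class-name map; taken from the sidecar if absent.
#' @return a [region_label_volume()].
#' @export
read_labels <- function(path, class_names = NULL) {
  x <- read_stack(path)
  if (is.null(class_names)) {
    sp <- if (dir.exists(path)) {
      f <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))[1]
      sidecar_path(f)
    } else sidecar_path(path)
    if (file.exists(sp)) {
      side <- jsonlite::read_json(sp, simplifyVector = TRUE)
      if (!is.null(side$class_names)) class_names <- unlist(side$class_names)
    }
  }
  if (is.null(class_names))
    stop("no class_names supplied and none found in sidecar", call. = FALSE)
  attr(x, "metadata") <- NULL
  region_label_volume(x, class_names)
}
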