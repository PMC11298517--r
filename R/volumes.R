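#' Multi-channel volume
#'
#' Bundles one 3D intensity array per excitation channel on a shared
#' voxel grid, with per-channel acquisition metadata. Axis order is
#' (z, y, x) throughout the package.
#'
#' @param channels named list of 3D arrays; names are excitation
#'   wavelengths (e.g. `"785"`). All arrays must share one shape and
#'   contain finite, nonnegative intensities.
#' @param metadata named list of [acquisition_metadata()] matching
#'   `channels`; built from [default_channel_config()] if omitted.
#' @return an object of class `multichannel_volume`.
#' @export
multichannel_volume <- function(channels, metadata = NULL) {
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)))
    stop("channels must be a non-empty named list of 3D arrays", call. = FALSE)
  channels <- lapply(channels, as_stack3d)
  for (nm in names(channels)) stopifnot_3d(channels[[nm]], paste0("channel ", nm))
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all channel arrays must share an identical shape", call. = FALSE)
  for (nm in names(channels)) {
    v <- channels[[nm]]
    if (any(!is.finite(v))) stop("channel ", nm, " contains non-finite values",
                                 call. = FALSE)
    if (min(v) < 0) stop("channel ", nm, " contains negative intensities",
                         call. = FALSE)
  }
  if (is.null(metadata)) {
    metadata <- default_channel_config()[names(channels)]
    if (any(vapply(metadata, is.null, logical(1))))
      stop("channel names must be known wavelengths or metadata supplied",
           call. = FALSE)
  }
  if (!identical(sort(names(metadata)), sort(names(channels))))
    stop("metadata names must match channel names", call. = FALSE)
  structure(list(channels = channels, metadata = metadata[names(channels)]),
            class = "multichannel_volume")
}

#' @export
print.multichannel_volume <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<multichannel_volume> %d channel(s) [%s] | shape %d x %d x %d (z,y,x)\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2], d[3]))
  invisible(x)
}

#' Voxel size of a multi-channel volume
#' @param x a `multichannel_volume`.
#' @return numeric `c(z, y, x)` voxel size in micrometres.
#' @export
voxel_size <- function(x) {
  stopifnot(inherits(x, "multichannel_volume"))
  x$metadata[[1]]$voxel_size_um
}

#' Region label volume
#'
#' Integer-coded 3D segmentation (ground truth, manual delineation or
#' prediction). Code 0 is reserved for unlabeled/ignore voxels; every
#' nonzero code must be named in `class_names`.
#'
#' @param labels 3D integer array (z, y, x).
#' @param class_names named character vector mapping code (as name) to
#'   class name, e.g. `c("1" = "background", "2" = "lumen")`.
#' @return an object of class `region_label_volume`.
#' @export
region_label_volume <- function(labels, class_names) {
  labels <- as_stack3d(labels)
  stopifnot_3d(labels, "labels")
  storage.mode(labels) <- "integer"
  if (is.null(names(class_names)) || any(names(class_names) == ""))
    stop("class_names must be named by integer code", call. = FALSE)
  codes <- sort(unique(as.vector(labels)))
  codes <- codes[codes != 0L]
  missing <- setdiff(as.character(codes), names(class_names))
  if (length(missing) > 0L)
    stop("label codes without class name: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if ("0" %in% names(class_names))
    stop("code 0 is reserved for unlabeled voxels", call. = FALSE)
  structure(list(labels = labels,
                 class_names = vapply(class_names, as.character, character(1))),
            class = "region_label_volume")
}

#' @export
print.region_label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<region_label_volume> shape %d x %d x %d | classes: %s\n",
              d[1], d[2], d[3],
              paste(sprintf("%s=%s", names(x$class_names), x$class_names),
                    collapse = ", ")))
  invisible(x)
}

#' Binary mask of one class in a label volume
#' @param x a `region_label_volume`.
#' @param class class name (as in `class_names`).
#' @return logical 3D array.
#' @export
class_mask <- function(x, class) {
  stopifnot(inherits(x, "region_label_volume"))
  hit <- names(x$class_names)[x$class_names == class]
  if (length(hit) == 0L) stop("unknown class: ", class, call. = FALSE)
  array(x$labels %in% as.integer(hit), dim = dim(x$labels))
}
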