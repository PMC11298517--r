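# Acquisition-to-analysis conditioning: bilateral fusion by digital
# addition, trilinear (block-average) downsampling, exposure
# normalization and percentile histogram normalization.

#' Fuse bilateral acquisitions by digital addition
#'
#' Combines separately acquired left- and right-illuminated stacks of
#' the same channel by elementwise addition in 32-bit-float semantics.
#' No saturation is applied; the fraction of voxels whose sum would
#' exceed the input integer range is reported as a diagnostic.
#'
#' @param left,right 3D arrays of identical shape (or the respective
#'   channels read by [read_stack()]).
#' @param dtype_max saturation level of the input pixel type; default
#'   65535 when both inputs are integer, otherwise `Inf`.
#' @return an object of class `fusion_result`: list with `fused`
#'   (double array), `provenance` and `clipped_fraction`.
#' @export
fuse_bilateral <- function(left, right, dtype_max = NULL) {
  ml <- attr(left, "metadata"); mr <- attr(right, "metadata")
  if (!is.null(ml) && !is.null(mr) &&
      ml$excitation_nm != mr$excitation_nm)
    stop("cannot fuse different excitation channels (",
         ml$excitation_nm, " vs ", mr$excitation_nm, " nm)", call. = FALSE)
  left <- as_stack3d(left); right <- as_stack3d(right)
  if (!identical(dim(left), dim(right)))
    stop("shape mismatch between left and right stacks", call. = FALSE)
  if (is.null(dtype_max))
    dtype_max <- if (is.integer(left) && is.integer(right)) 65535 else Inf
  fused <- array(as.double(left) + as.double(right), dim = dim(left))
  meta <- ml
  if (!is.null(meta)) meta$side <- "fused"
  structure(list(fused = fused,
                 provenance = list(left = deparse(substitute(left)),
                                   right = deparse(substitute(right))),
                 clipped_fraction = mean(fused > dtype_max),
                 metadata = meta),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  d <- dim(x$fused)
  cat(sprintf("<fusion_result> %d x %d x %d | clipped_fraction %.4g\n",
              d[1], d[2], d[3], x$clipped_fraction))
  invisible(x)
}

#' Fuse two multi-channel volumes channel by channel
#'
#' @param left,right `multichannel_volume` objects with matching
#'   channels.
#' @return a `multichannel_volume` of fused channels; per-channel
#'   clipped fractions are attached as attribute `"clipped_fraction"`.
#' @export
fuse_volumes <- function(left, right) {
  stopifnot(inherits(left, "multichannel_volume"),
            inherits(right, "multichannel_volume"))
  if (!identical(names(left$channels), names(right$channels)))
    stop("channel sets differ between sides", call. = FALSE)
  clipped <- numeric(0)
  fused <- lapply(names(left$channels), function(ch) {
    fr <- fuse_bilateral(left$channels[[ch]], right$channels[[ch]])
    clipped[[ch]] <<- fr$clipped_fraction
    fr$fused
  })
  names(fused) <- names(left$channels)
  meta <- lapply(left$metadata, function(m) { m$side <- "fused"; m })
  out <- multichannel_volume(fused, meta)
  attr(out, "clipped_fraction") <- clipped
  out
}

# block-average one axis of a 3D array by integer factor f,
# averaging trailing partial blocks over the voxels present
.downsample_axis <- function(x, f, axis) {
  if (f == 1L) return(x)
  d <- dim(x)
  n <- d[axis]
  groups <- ceiling(seq_len(n) / f)
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  dim(xp) <- c(n, prod(d[perm[2:3]]))
  sums <- rowsum(xp, groups, reorder = TRUE)
  counts <- as.vector(table(groups))
  means <- sums / counts
  dim(means) <- c(length(counts), d[perm[2]], d[perm[3]])
  aperm(means, order(perm))
}

#' Downsample a volume by trilinear (block) averaging
#'
#' Each output voxel is the arithmetic mean of its
#' `factor[1] x factor[2] x factor[3]` input block; trailing partial
#' blocks are averaged over the voxels present (no padding). The
#' canonical use is reducing 5 um isotropic acquisitions to 20 um with
#' `factor = 4`.
#'
#' @param volume 3D array (z, y, x).
#' @param factor positive integer downsampling factor, scalar or
#'   per-axis `c(z, y, x)`.
#' @return 3D array; if the input carries `"metadata"`, its voxel size
#'   is multiplied by `factor`.
#' @export
downsample_trilinear <- function(volume, factor) {
  meta <- attr(volume, "metadata")
  volume <- as_stack3d(volume)
  stopifnot_3d(volume)
  factor <- as.integer(factor)
  if (length(factor) == 1L) factor <- rep(factor, 3L)
  if (length(factor) != 3L || any(is.na(factor)) || any(factor < 1L))
    stop("factor must be positive integers (scalar or per axis)", call. = FALSE)
  out <- volume
  storage.mode(out) <- "double"
  for (ax in 1:3) out <- .downsample_axis(out, factor[ax], ax)
  if (!is.null(meta)) {
    meta$voxel_size_um <- meta$voxel_size_um * factor
    attr(out, "metadata") <- meta
  }
  out
}

#' Downsample every channel of a multi-channel volume
#'
#' @param mcv a `multichannel_volume`.
#' @param factor as in [downsample_trilinear()].
#' @return a `multichannel_volume` with updated voxel size.
#' @export
downsample_volume <- function(mcv, factor) {
  stopifnot(inherits(mcv, "multichannel_volume"))
  factor <- as.integer(factor)
  if (length(factor) == 1L) factor <- rep(factor, 3L)
  chans <- lapply(mcv$channels, downsample_trilinear, factor = factor)
  meta <- lapply(mcv$metadata, function(m) {
    m$voxel_size_um <- m$voxel_size_um * factor; m
  })
  multichannel_volume(chans, meta)
}

# nearest-voxel label downsampling (block representative = first voxel)
downsample_labels <- function(rlv, factor) {
  stopifnot(inherits(rlv, "region_label_volume"))
  factor <- as.integer(factor)
  if (length(factor) == 1L) factor <- rep(factor, 3L)
  d <- dim(rlv$labels)
  idx <- lapply(1:3, function(ax) seq(1L, d[ax], by = factor[ax]))
  region_label_volume(rlv$labels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
                      rlv$class_names)
}

#' Normalize intensities by exposure time
#'
#' Divides intensities by the channel exposure so values become counts
#' per millisecond, making channels with different exposure (104 ms vs
#' 1040 ms at 785 nm) comparable.
#'
#' @param volume 3D array.
#' @param metadata [acquisition_metadata()] for the channel.
#' @return double array with updated `"metadata"` (flagged normalized).
#' @export
normalize_exposure <- function(volume, metadata = attr(volume, "metadata")) {
  if (is.null(metadata)) stop("metadata with exposure_ms required", call. = FALSE)
  if (isTRUE(metadata$normalized))
    stop("volume is already exposure-normalized; refusing to divide twice",
         call. = FALSE)
  out <- volume / metadata$exposure_ms
  metadata$normalized <- TRUE
  attr(out, "metadata") <- metadata
  out
}

#' Percentile histogram normalization
#'
#' Linear rescale mapping the `p_low` percentile to 0 and the `p_high`
#' percentile to 1, with values clipped into \[0, 1\]. This is the
#' conditioning applied before digital channel subtraction.
#'
#' @param volume numeric array.
#' @param p_low,p_high percentiles in \[0, 100), `p_low < p_high`.
#' @return array of the same shape with values in \[0, 1\]. A constant
#'   input has zero dynamic range and returns all zeros with a warning.
#' @export
normalize_histogram <- function(volume, p_low = 0.1, p_high = 99.9) {
  if (!(p_low >= 0 && p_low < p_high && p_high <= 100))
    stop("require 0 <= p_low < p_high <= 100", call. = FALSE)
  q <- quantile(volume, probs = c(p_low, p_high) / 100, names = FALSE)
  if (q[2] <= q[1]) {
    warning("zero dynamic range between percentiles; returning all zeros")
    return(array(0, dim = dim(volume)))
  }
  out <- (volume - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  attr(out, "metadata") <- attr(volume, "metadata")
  out
}
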