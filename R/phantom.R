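# Synthetic liver / biopsy / edge phantoms with ground-truth labels.
# The generator emulates what unstained cleared liver looks like under
# five excitation lasers: parenchyma split into interleaved high- and
# low-autofluorescence zones (zonation-like), dark vessel lumina, image
# background, per-channel intensity ratios peaking at 785 nm, exponential
# depth attenuation, one-sided illumination shading per acquisition side,
# and heteroscedastic sensor noise.

PHANTOM_CLASSES <- c("background", "lumen", "low_AF", "high_AF")

#' Default class-by-channel autofluorescence signature
#'
#' Mean clean intensity (arbitrary units, max 1) of each phantom class
#' in each excitation channel. Liver parenchyma is brightest at 785 nm;
#' the high:low AF zone contrast is 2:1. Lumen intensity equals the
#' background level (vessels carry no tissue signal).
#'
#' @param background_level intensity of background and lumen voxels.
#' @return 4 x 5 matrix, rows `background, lumen, low_AF, high_AF`,
#'   columns the excitation wavelengths.
#' @export
default_class_signature <- function(background_level = 0.02) {
  S <- rbind(background = rep(background_level, 5),
             lumen      = rep(background_level, 5),
             low_AF     = c(0.15, 0.18, 0.20, 0.25, 0.50),
             high_AF    = c(0.30, 0.36, 0.40, 0.50, 1.00))
  colnames(S) <- as.character(AF_WAVELENGTHS)
  S
}

#' Phantom specification
#'
#' Parameters of the synthetic tissue generator. All physical sizes are
#' in micrometres and converted through `voxel_size_um`.
#'
#' @param shape_voxels volume shape `c(z, y, x)` in voxels.
#' @param voxel_size_um voxel size `c(z, y, x)` in micrometres.
#' @param class_signature nonnegative matrix of mean clean intensities,
#'   rows at least `background, lumen, low_AF, high_AF`, columns the
#'   excitation channels; see [default_class_signature()].
#' @param zonation_period_um spatial alternation scale of the high/low
#'   AF parenchymal zones.
#' @param vessel_count number of random-walk vessel tubes.
#' @param vessel_radius_um range `c(min, max)` of per-branch tube radii.
#' @param attenuation_length_um exponential decay length of signal with
#'   depth along the detection (z) axis; `Inf` disables attenuation.
#' @param illumination_decay_um decay length of the one-sided light-sheet
#'   shading along x; `Inf` disables shading.
#' @param gaussian_sd Gaussian read-noise sd as a *fraction of the local
#'   clean signal* (e.g. 0.05 = 5% noise).
#' @param poisson_scale photon count per intensity unit for shot noise;
#'   0 disables the Poisson component.
#' @param background_level clean intensity of background/lumen voxels.
#' @param seed integer; fully determines the generated volumes.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape_voxels = c(64, 256, 256),
                         voxel_size_um = c(20, 20, 20),
                         class_signature = default_class_signature(background_level),
                         zonation_period_um = 600,
                         vessel_count = 25,
                         vessel_radius_um = c(40, 100),
                         attenuation_length_um = 2000,
                         illumination_decay_um = 3000,
                         gaussian_sd = 0.05,
                         poisson_scale = 0,
                         background_level = 0.02,
                         seed = 1L) {
  shape_voxels <- as.integer(shape_voxels)
  if (length(shape_voxels) != 3L || any(shape_voxels < 1L))
    stop("shape_voxels must be three positive integers", call. = FALSE)
  if (any(voxel_size_um <= 0)) stop("voxel_size_um must be positive", call. = FALSE)
  if (min(class_signature) < 0)
    stop("class_signature entries must be nonnegative", call. = FALSE)
  if (!all(PHANTOM_CLASSES %in% rownames(class_signature)))
    stop("class_signature must include rows ",
         paste(PHANTOM_CLASSES, collapse = ", "), call. = FALSE)
  if (gaussian_sd < 0 || poisson_scale < 0)
    stop("noise parameters must be nonnegative", call. = FALSE)
  if (length(vessel_radius_um) == 1L)
    vessel_radius_um <- rep(vessel_radius_um, 2L)
  if (any(vessel_radius_um <= 0) || vessel_radius_um[1] > vessel_radius_um[2])
    stop("vessel_radius_um must be a positive range c(min, max)", call. = FALSE)
  if (2 * vessel_radius_um[2] > min(shape_voxels * voxel_size_um))
    stop("vessel radius larger than volume", call. = FALSE)
  structure(list(shape_voxels = shape_voxels,
                 voxel_size_um = as.numeric(voxel_size_um),
                 class_signature = class_signature,
                 zonation_period_um = zonation_period_um,
                 vessel_count = as.integer(vessel_count),
                 vessel_radius_um = as.numeric(vessel_radius_um),
                 attenuation_length_um = attenuation_length_um,
                 illumination_decay_um = illumination_decay_um,
                 gaussian_sd = gaussian_sd,
                 poisson_scale = poisson_scale,
                 background_level = background_level,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# one-sided light-sheet shading profile along x (length nx), decaying
# from the illuminated border; side "right" mirrors side "left"
illumination_profile <- function(nx, vx_um, decay_um, side = c("left", "right")) {
  side <- match.arg(side)
  if (!is.finite(decay_um)) return(rep(1, nx))
  x_um <- (seq_len(nx) - 1) * vx_um
  p <- exp(-x_um / decay_um)
  if (side == "right") rev(p) else p
}

# exponential depth attenuation along z (detection axis)
attenuation_profile <- function(nz, vz_um, length_um) {
  if (!is.finite(length_um)) return(rep(1, nz))
  exp(-((seq_len(nz) - 1) * vz_um) / length_um)
}

# smooth pseudo-periodic zonation field: sum of random-direction 3D
# cosines with wavelength ~ period; thresholded at 0 into high/low zones
.zonation_field <- function(shape, voxel, period_um, n_waves = 4L) {
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  zc <- (seq_len(nz) - 1) * voxel[1]
  yc <- (seq_len(ny) - 1) * voxel[2]
  xc <- (seq_len(nx) - 1) * voxel[3]
  f <- array(0, dim = shape)
  for (i in seq_len(n_waves)) {
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    k <- 2 * pi / period_um
    phi <- runif(1, 0, 2 * pi)
    # separable accumulation of cos(k d.(z,y,x) + phi) via outer sums
    ph <- outer(k * d[1] * zc, k * d[2] * yc, "+")
    f <- f + cos(outer(ph, k * d[3] * xc + phi, "+"))
  }
  f
}

# rasterize vessel random-walk tubes; returns logical (z,y,x) mask
.vessel_mask <- function(shape, voxel, count, radius_um) {
  mask <- array(FALSE, dim = shape)
  if (count == 0L) return(mask)
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  for (v in seq_len(count)) {
    r_um <- runif(1, radius_um[1], radius_um[2])
    rz <- max(1L, ceiling(r_um / voxel[1]))
    ry <- max(1L, ceiling(r_um / voxel[2]))
    rx <- max(1L, ceiling(r_um / voxel[3]))
    pos <- c(runif(1, 1, nz), runif(1, 1, ny), runif(1, 1, nx))
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    n_steps <- ceiling(0.6 * max(ny, nx))
    # precompute local ellipsoid offsets once per vessel
    oz <- -rz:rz; oy <- -ry:ry; ox <- -rx:rx
    ell <- which(outer(outer((oz * voxel[1])^2, (oy * voxel[2])^2, "+"),
                       (ox * voxel[3])^2, "+") <= r_um^2, arr.ind = TRUE)
    offs <- cbind(oz[ell[, 1]], oy[ell[, 2]], ox[ell[, 3]])
    for (s in seq_len(n_steps)) {
      ctr <- round(pos)
      vox <- cbind(offs[, 1] + ctr[1], offs[, 2] + ctr[2], offs[, 3] + ctr[3])
      keep <- vox[, 1] >= 1 & vox[, 1] <= nz &
              vox[, 2] >= 1 & vox[, 2] <= ny &
              vox[, 3] >= 1 & vox[, 3] <= nx
      if (any(keep)) mask[vox[keep, , drop = FALSE]] <- TRUE
      dir <- dir + 0.25 * rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      pos <- pos + dir * 2
      if (all(pos < 1) || all(pos > c(nz, ny, nx))) break
    }
  }
  mask
}

# assemble truth labels for liver texture inside an organ mask
.liver_truth <- function(spec, organ) {
  shape <- spec$shape_voxels
  zon <- .zonation_field(shape, spec$voxel_size_um, spec$zonation_period_um)
  vess <- .vessel_mask(shape, spec$voxel_size_um, spec$vessel_count,
                       spec$vessel_radius_um)
  labels <- array(1L, dim = shape)                    # background
  labels[organ & zon <= 0] <- 3L                      # low_AF
  labels[organ & zon > 0] <- 4L                       # high_AF
  labels[organ & vess] <- 2L                          # lumen
  labels
}

# clean (noise-free, unshaded) per-channel intensities from truth labels
.clean_channels <- function(labels, S) {
  classes <- PHANTOM_CLASSES
  chans <- colnames(S)
  lut <- S[classes, , drop = FALSE]
  out <- lapply(chans, function(ch) {
    v <- lut[, ch][labels]            # labels index rows 1..4
    array(v, dim = dim(labels))
  })
  names(out) <- chans
  out
}

# apply depth attenuation, one-sided shading and sensor noise
.acquire_side <- function(clean, spec, side) {
  shape <- spec$shape_voxels
  att <- attenuation_profile(shape[1], spec$voxel_size_um[1],
                             spec$attenuation_length_um)
  ill <- illumination_profile(shape[3], spec$voxel_size_um[3],
                              spec$illumination_decay_um, side)
  field <- att %o% rep(1, shape[2]) %o% ill
  out <- lapply(clean, function(v) {
    x <- v * field
    if (spec$poisson_scale > 0)
      x <- rpois(length(x), lambda = spec$poisson_scale * x) / spec$poisson_scale
    if (spec$gaussian_sd > 0)
      x <- x + rnorm(length(x), sd = spec$gaussian_sd * v * field)
    array(pmax(x, 0), dim = shape)
  })
  out
}

.phantom_metadata <- function(spec, side) {
  cfg <- default_channel_config(voxel_size_um = spec$voxel_size_um)
  lapply(cfg, function(m) { m$side <- side; m })
}

.phantom_from_truth <- function(labels, spec) {
  clean <- .clean_channels(labels, spec$class_signature)
  left  <- .acquire_side(clean, spec, "left")
  right <- .acquire_side(clean, spec, "right")
  cn <- stats::setNames(PHANTOM_CLASSES, as.character(1:4))
  list(left  = multichannel_volume(left,  .phantom_metadata(spec, "left")),
       right = multichannel_volume(right, .phantom_metadata(spec, "right")),
       truth = region_label_volume(labels, cn),
       clean = multichannel_volume(clean, .phantom_metadata(spec, "fused")),
       spec  = spec)
}

#' Generate a synthetic liver phantom
#'
#' Produces left- and right-illuminated multi-channel acquisitions of a
#' liver-like volume plus the ground-truth label volume. The organ is an
#' ellipsoid of parenchyma split into interleaved high/low AF zones with
#' dark vessel lumina; background surrounds it. The two sides share the
#' same clean tissue and depth attenuation but apply mirror-image
#' illumination shading, then independent noise.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `left`, `right` (class
#'   `multichannel_volume`), `truth` (class `region_label_volume`),
#'   `clean` (the noise-free, unshaded volume) and `spec`.
#' @examples
#' ph <- generate_liver_phantom(phantom_spec(shape_voxels = c(8, 32, 32)))
#' ph$truth
#' @export
generate_liver_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    shape <- spec$shape_voxels
    zc <- (seq_len(shape[1]) - (shape[1] + 1) / 2) / (shape[1] / 2)
    yc <- (seq_len(shape[2]) - (shape[2] + 1) / 2) / (shape[2] / 2)
    xc <- (seq_len(shape[3]) - (shape[3] + 1) / 2) / (shape[3] / 2)
    # inscribed ellipsoid organ occupying most of the field of view
    organ <- outer(outer(zc^2 / 0.96^2, yc^2 / 0.88^2, "+"),
                   xc^2 / 0.88^2, "+") <= 1
    labels <- .liver_truth(spec, organ)
    .phantom_from_truth(labels, spec)
  })
}

#' Generate a synthetic biopsy-core phantom
#'
#' A liver-textured cylinder along the long (x) axis, emulating the
#' ~1 mm tissue cores extracted by percutaneous biopsy needles;
#' everything outside the cylinder is background.
#'
#' @param spec a [phantom_spec()].
#' @param diameter_um cylinder diameter in micrometres (default the
#'   clinical 1 mm maximum).
#' @param length_um cylinder length in micrometres; defaults to 90% of
#'   the x extent.
#' @return same structure as [generate_liver_phantom()].
#' @export
generate_biopsy_phantom <- function(spec = phantom_spec(),
                                    diameter_um = 1000,
                                    length_um = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape_voxels; voxel <- spec$voxel_size_um
  if (is.null(length_um)) length_um <- 0.9 * shape[3] * voxel[3]
  if (diameter_um > min(shape[1] * voxel[1], shape[2] * voxel[2]) ||
      length_um > shape[3] * voxel[3])
    stop("cylinder does not fit inside shape_voxels", call. = FALSE)
  with_seed(spec$seed, {
    zc <- (seq_len(shape[1]) - (shape[1] + 1) / 2) * voxel[1]
    yc <- (seq_len(shape[2]) - (shape[2] + 1) / 2) * voxel[2]
    xc <- (seq_len(shape[3]) - (shape[3] + 1) / 2) * voxel[3]
    in_section <- outer(zc^2, yc^2, "+") <= (diameter_um / 2)^2
    in_length <- abs(xc) <= length_um / 2
    cyl <- array(as.vector(in_section) & rep(in_length, each = shape[1] * shape[2]),
                 dim = shape)
    labels <- .liver_truth(spec, cyl)
    .phantom_from_truth(labels, spec)
  })
}

#' Generate a blurred-edge phantom
#'
#' An ideal intensity step along x at the volume mid-plane, convolved
#' with an isotropic Gaussian (applied in closed form), used as analytic
#' ground truth for edge-rise-distance measurements: the 10-90% rise
#' distance of the profile is 2 x 1.2816 x sigma pixels.
#'
#' @param sigma_blur_px Gaussian sigma in pixels; 0 gives an exact step.
#' @param low,high intensities of the two plateaus (`high > low`).
#' @param shape volume shape `c(z, y, x)`.
#' @return 3D array (z, y, x).
#' @export
generate_edge_phantom <- function(sigma_blur_px, low = 0, high = 1,
                                  shape = c(4, 16, 64)) {
  if (high <= low) stop("high must exceed low", call. = FALSE)
  if (sigma_blur_px < 0) stop("sigma_blur_px must be nonnegative", call. = FALSE)
  shape <- as.integer(shape)
  x <- (seq_len(shape[3]) - 0.5) - shape[3] / 2   # distance from mid-plane
  prof <- if (sigma_blur_px == 0) ifelse(x < 0, low, high)
          else low + (high - low) * pnorm(x / sigma_blur_px)
  array(rep(prof, each = shape[1] * shape[2]), dim = shape)
}
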