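#' Acquisition channels supported by the pipeline
#'
#' Excitation wavelengths (nm) of the five-laser light-sheet setup the
#' pipeline models.
#' @export
AF_WAVELENGTHS <- c(405L, 488L, 561L, 640L, 785L)

# emission filters matched to each excitation laser
.default_filters <- c("405" = "525/50", "488" = "535/30", "561" = "620/20",
                      "640" = "680/30", "785" = "845/55")

#' Acquisition metadata for one excitation channel
#'
#' Describes how a single-channel stack was acquired: excitation
#' wavelength, emission filter, exposure, laser power, voxel size and
#' illumination side.
#'
#' @param excitation_nm excitation wavelength in nm; one of 405, 488,
#'   561, 640, 785.
#' @param emission_filter emission filter token, e.g. `"525/50"`.
#' @param exposure_ms exposure time in milliseconds (> 0).
#' @param laser_power laser power in arbitrary units (>= 0).
#' @param voxel_size_um voxel size in micrometres as `c(z, y, x)` (> 0).
#' @param side illumination side: `"left"`, `"right"` or `"fused"`.
#' @return an object of class `acquisition_metadata`.
#' @examples
#' acquisition_metadata(785, exposure_ms = 1040)
#' @export
acquisition_metadata <- function(excitation_nm,
                                 emission_filter = NULL,
                                 exposure_ms = 104,
                                 laser_power = 1,
                                 voxel_size_um = c(20, 20, 20),
                                 side = c("fused", "left", "right")) {
  excitation_nm <- as.integer(excitation_nm)
  if (!excitation_nm %in% AF_WAVELENGTHS)
    stop("unknown excitation wavelength: ", excitation_nm,
         " (expected one of ", paste(AF_WAVELENGTHS, collapse = ", "), ")",
         call. = FALSE)
  if (is.null(emission_filter))
    emission_filter <- unname(.default_filters[as.character(excitation_nm)])
  side <- match.arg(side)
  exposure_ms <- as.numeric(exposure_ms)
  laser_power <- as.numeric(laser_power)
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3L)
  if (length(exposure_ms) != 1L || !is.finite(exposure_ms) || exposure_ms <= 0)
    stop("exposure_ms must be a single positive number", call. = FALSE)
  if (length(laser_power) != 1L || !is.finite(laser_power) || laser_power < 0)
    stop("laser_power must be a single nonnegative number", call. = FALSE)
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0))
    stop("voxel_size_um must be three positive numbers (z, y, x)",
         call. = FALSE)
  structure(
    list(excitation_nm = excitation_nm,
         emission_filter = as.character(emission_filter),
         exposure_ms = exposure_ms,
         laser_power = laser_power,
         voxel_size_um = voxel_size_um,
         side = side,
         normalized = FALSE),
    class = "acquisition_metadata")
}

#' @export
print.acquisition_metadata <- function(x, ...) {
  cat(sprintf("<acquisition_metadata> %d nm | filter %s | %g ms | side %s | voxel %s um\n",
              x$excitation_nm, x$emission_filter, x$exposure_ms, x$side,
              paste(x$voxel_size_um, collapse = "x")))
  invisible(x)
}

#' Default five-channel acquisition configuration
#'
#' The standard setup: lasers 405/488/561/640/785 nm matched with the
#' 525/50, 535/30, 620/20, 680/30 and 845/55 emission filters; 104 ms
#' exposure for all channels except 1040 ms at 785 nm.
#'
#' @param voxel_size_um voxel size applied to every channel.
#' @return named list of [acquisition_metadata()], keyed by wavelength.
#' @export
default_channel_config <- function(voxel_size_um = c(20, 20, 20)) {
  cfg <- lapply(AF_WAVELENGTHS, function(w) {
    acquisition_metadata(w,
                         exposure_ms = if (w == 785L) 1040 else 104,
                         voxel_size_um = voxel_size_um)
  })
  names(cfg) <- as.character(AF_WAVELENGTHS)
  cfg
}

#' Load a channel configuration from YAML or JSON
#'
#' Reads a per-channel acquisition config: a mapping from excitation
#' wavelength to `emission_filter`, `exposure_ms`, `laser_power` and
#' `voxel_size_um` records. Missing fields fall back to the defaults of
#' [default_channel_config()].
#'
#' @param path path to a YAML (`.yml`/`.yaml`) or JSON file.
#' @return named list of [acquisition_metadata()], keyed by wavelength.
#' @export
load_channel_config <- function(path) {
  if (!file.exists(path)) stop("channel config not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw) || length(raw) == 0L)
    stop("channel config is empty: ", path, call. = FALSE)
  if (is.null(names(raw)) || any(names(raw) == ""))
    stop("channel config must map excitation wavelengths to records",
         call. = FALSE)
  cfg <- lapply(names(raw), function(key) {
    rec <- raw[[key]]
    wl <- suppressWarnings(as.integer(key))
    if (is.na(wl)) stop("unknown wavelength key: ", key, call. = FALSE)
    acquisition_metadata(
      wl,
      emission_filter = rec$emission_filter,
      exposure_ms = if (!is.null(rec$exposure_ms)) rec$exposure_ms
                    else if (wl == 785L) 1040 else 104,
      laser_power = if (!is.null(rec$laser_power)) rec$laser_power else 1,
      voxel_size_um = if (!is.null(rec$voxel_size_um)) rec$voxel_size_um
                      else c(20, 20, 20),
      side = if (!is.null(rec$side)) rec$side else "fused")
  })
  names(cfg) <- as.character(vapply(cfg, `[[`, integer(1), "excitation_nm"))
  cfg
}
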