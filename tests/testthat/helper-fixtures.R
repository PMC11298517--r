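# Shared fixtures: small phantoms and configs sized for fast tests.

tiny_spec <- function(seed = 1L, ...) {
  phantom_spec(shape_voxels = c(16, 48, 48),
               voxel_size_um = c(20, 20, 20),
               zonation_period_um = 400,
               vessel_count = 5,
               vessel_radius_um = c(30, 60),
               seed = seed, ...)
}

noiseless_spec <- function(seed = 1L, ...) {
  tiny_spec(seed = seed, gaussian_sd = 0, poisson_scale = 0,
            attenuation_length_um = Inf, illumination_decay_um = Inf, ...)
}

small_config <- function(...) feature_bank_config(max_sigma = 4, ...)

# fuse both sides of a phantom into one multichannel volume
fuse_phantom <- function(ph) fuse_volumes(ph$left, ph$right)

# sparse annotation fixture via the package-internal simulated annotator
sparse_annot <- function(ph, slices, n = 150L, seed = 1L) {
  afspectra:::.sparse_annotation(ph$truth, slices, n_per_class = n, seed = seed)
}
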