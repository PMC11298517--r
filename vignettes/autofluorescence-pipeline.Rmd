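---
title: "Quantifying tissue autofluorescence in light-sheet volumes"
author: "afspectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tissue autofluorescence in light-sheet volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afspectra)
```

## The problem

Optically cleared, *unstained* tissue emits intrinsic autofluorescence
(AF) whose intensity varies strongly with excitation wavelength and
anatomical region. In light-sheet fluorescence microscopy (LSFM) this
signal — usually treated as a nuisance — can be exploited for label-free
tissue characterization: each region has a spectral signature across
excitation channels (405, 488, 561, 640, 785 nm), and the 785 nm channel
of liver shows a zonation-like pattern of alternating high- and low-AF
parenchyma that supports machine-learning segmentation of unstained
organs and biopsy cores.

`afspectra` implements the computational side of that workflow:
acquisition fusion and downsampling, edge profiling, spectral
signatures, digital subtraction channels, an objective sharpness
statistic, and trainable pixel classification with probability-map
postprocessing and DICE evaluation. Because raw animal volumes are not
redistributable, the package ships a synthetic phantom generator that
emulates the salient structure of these data, so the whole chain runs,
and is tested, end to end.

## Preprocessing model

Bilateral LSFM acquires each plane twice, illuminated from the left and
from the right. The two stacks are combined by *digital addition*,
performed here in 64-bit floating point with **no saturation**: the sum
of two 16-bit stacks can exceed 65535, so `fuse_bilateral()` reports the
fraction of voxels that would have saturated (`clipped_fraction`) but
never clips. This preserves quantitation for the signature stage.

Downsampling (typically 5 µm → 20 µm isotropic, factor 4) is block
averaging: each output voxel is the arithmetic mean of its
`f_z × f_y × f_x` input block. Trailing partial blocks are averaged over
the voxels actually present rather than zero-padded, which avoids
darkened edges; as a consequence the global mean is conserved exactly
only when the factors divide the shape evenly.

Two normalizations are available:

* `normalize_exposure()` divides by the exposure time (104 ms for
  405–640 nm, 1040 ms at 785 nm), giving counts·ms⁻¹. It refuses to run
  twice on the same stack.
* `normalize_histogram()` — "histogram normalization" here means a
  percentile-clipped linear rescale: the `p_low` (default 0.1) and
  `p_high` (default 99.9) percentiles map to 0 and 1 and values are
  clipped to [0, 1]. Full histogram *equalization* was deliberately
  rejected: it is non-linear and would distort the semantics of the
  digital subtraction channels that consume the normalized volumes.
  This interpretation is recorded in every run log.

## Edge-rise-distance (ERD) profiles

An ERD profile is the sequence of pixel intensities along a line within
one slice, used to quantify the transition across a tissue boundary
(e.g. retina to lens). `extract_erd_profile()` samples at unit steps —
nearest voxel for axis-aligned lines, bilinear interpolation otherwise.
Replicates (one profile per animal) are aggregated by
`aggregate_profiles()` into a per-position mean with a 95% confidence
interval, mean ± t(n−1, 0.975)·sd/√n. The *t* interval, not the normal,
is used because replicate counts in this setting are small (3–4
animals).

Profiles are scalarized by `rise_distance()`: the distance between the
first crossings of the 10% and 90% fractional levels of the profile's
own range, linearly interpolated between samples. This scalar is an
extension of the profile readout (the profile itself carries no single
number); the fractions are configurable. For a step edge blurred by an
isotropic Gaussian of width σ the 10–90% distance is
2·z₀.₉·σ ≈ 2.5631·σ pixels, which `generate_edge_phantom()` provides as
analytic ground truth; the measured distance agrees within 2% for
σ ∈ [2, 8] px (the residual is sampling/interpolation error).

## Spectral signatures

`region_signature()` computes, per labeled region and channel, the mean
intensity minus the background-region mean (floored at 0), then
normalizes. The default `per_channel_max` normalization scales each
channel so its brightest region is 1, matching the per-channel color
bars used to display "relative AF characteristics"; `global_max` and
`none` are available when absolute comparisons across channels are
wanted (in that case, exposure normalization should be applied first,
and whether it was applied is part of the result's metadata story).
The uncorrected means are retained alongside, since background itself
is a displayed region.

## Digital subtraction channels

`subtract_channels(a, b, normalize_first = TRUE)` histogram-normalizes
both inputs and returns `a − b` clipped at zero — the virtual channel
(e.g. 405−640 nm) that enhances structures whose AF spectra diverge.
`invert_volume()` produces the inverted subtraction highlighting the
complementary structures (cortical bone, marrow). Clipping at zero
means the two subtraction directions partition `|a − b|`.

## Fourier sharpness

The sharpness statistic is the standard deviation of the image's power
spectrum, read as a distribution over spatial frequency: each slice is
mean-subtracted, Hann-windowed and Fourier-transformed; the squared
magnitudes are normalized to unit total energy with the DC bin
excluded; the statistic is the standard deviation of radial frequency
(cycles/pixel) under that distribution — the spectral bandwidth.
Detail-rich slices hold power at high frequencies and score high;
Gaussian blur contracts the spectrum and strictly lowers the score.
Windowing suppresses spectral leakage from the non-periodic image
borders; mean subtraction plus energy normalization make the statistic
exactly invariant to affine intensity rescaling `a·I + b`, so channels
with different exposure or laser power do not trivially dominate.
Whether the original analysis windowed, log-transformed, or pooled per
volume is not specified anywhere; this contract is one consistent
choice and is flagged in output metadata. Note that the naive
alternative — the standard deviation of the normalized power *values* —
moves the wrong way (it grows as blur concentrates energy into few
bins), which is why the bandwidth reading is used.

## Trainable pixel classification

Segmentation follows the trainable-WEKA recipe: a multiscale 2D feature
bank feeds a random forest trained on sparse manual annotations.

**Feature bank.** Scales are the power-of-two ladder σ ∈ {1, 2, 4, 8,
16} (max sigma 16), plus σ = 0 meaning the raw image (min sigma 0).
Families: Gaussian smoothing, Gaussian-derivative gradient magnitude,
the two ordered Hessian eigenvalues, differences of Gaussians for **all**
sigma pairs (including pairs with the raw image), and membrane
projections — a 19×19, thickness-1 line kernel rotated over 30
orientations with the response stack aggregated by
sum/mean/max/min/median/sd. The default bank is 6+5+10+15+6 = **42
features**, pinned by a regression test. The reference tool reports 228
attributes for its (unlisted) feature selection; no attempt is made to
force that count — the composition here is the documented one above.
Filtering is FFT-based with replicate padding, and kernel frequency
responses are cached per slice shape, so whole volumes are filtered at
one forward transform per slice plus one inverse per filter. Kernel
supports are truncated when a kernel would exceed the slice.

**Training design.** Features are 2D (slice-wise), not 3D, because the
workflow annotates and trains on individual images; slice-wise
processing also bounds memory to a few feature planes. The canonical
design is five annotated slices from each of two samples (ten images,
two livers), 785 nm channel at 20 µm, four classes: background, lumen
(the entirety of vessels), low AF and high AF. The forest uses 200
trees, √p candidate features per split, and a recorded seed with
single-threaded prediction, making the whole train→predict→evaluate
chain bit-reproducible.

**Postprocessing.** Raw per-voxel class probabilities (vote fractions,
summing to 1) are postprocessed by subtracting the background-class
probability from each tissue class (clipped at 0) and replacing the
background map with its inversion 1 − P(background), the organ
gross-structure map. Negatives are clipped to keep maps in [0, 1]; the
original description does not say whether its implementation clipped,
and clipping is adopted here. Masks come from thresholding (default
0.5) or argmax; evaluation is per-class DICE, 2|A∩B|/(|A|+|B|), with
the both-empty case defined as 1 (flagged).

## The phantom generator

`generate_liver_phantom()` emulates what the analysis needs from real
data, not the physics of image formation:

* an ellipsoidal organ of parenchyma in empty background;
* *zonation*: a smooth pseudo-periodic field (sum of random-direction
  cosines with wavelength `zonation_period_um`, default 600 µm — the
  scale of hepatic lobules) thresholded into interleaved high/low AF
  zones. No quantitative zonation geometry is published, only the
  visual analogy to GS/E-Cadherin staining, so this is a geometric
  stand-in producing the two parenchymal classes the segmentation
  needs;
* *vessels*: random-walk tubes with per-branch radius (40–100 µm) whose
  lumina carry only background-level intensity — the liver's 785 nm
  pattern is attributed to vasculature, so vessels must be dark tubes;
* *spectra*: each class k has a mean clean intensity `S[k, c]` per
  channel c (`default_class_signature()`), with parenchyma brightest at
  785 nm and a 2:1 high:low zone contrast. The contrast ratio is a free
  choice — no numeric value is published — and lives in the preset, not
  in any assertion;
* *acquisition effects*: exponential depth attenuation along z
  (default length 2 mm), one-sided illumination shading along x
  (default 3 mm) mirrored between the left and right acquisitions, then
  noise;
* *noise*: optional Poisson shot noise plus Gaussian read noise whose
  sd is a **fraction of the local clean signal** (default 0.05 = 5%).
  The fractional form keeps the dim background (0.02) from clipping at
  zero, which an absolute sd of comparable size would do, and mimics
  the signal-dependence of shot noise.

Voxel intensities of a class are exactly `S[k, c]` before acquisition
effects, so with noise off and attenuation/shading disabled the
generator is an analytic oracle: masked means equal the signature table
exactly, which is what the signature-recovery tests assert. A fixed
seed makes output bit-identical; class geometry is independent of noise
and illumination parameters.

`generate_biopsy_phantom()` wraps the same texture in a cylinder along
x (default diameter 1 mm — the clinical percutaneous core size — i.e.
radius 25 voxels at 20 µm). `generate_edge_phantom()` is the analytic
Gaussian-blurred step used by the ERD tests.

What the phantoms do **not** model: refractive-index mismatch, stripe
artifacts from absorbing particles, bleed-through from stained
structures, scattering PSF anisotropy, or real zonation geometry.
Passing tests therefore demonstrate correctness of the *computations*
and recoverability under the stated noise model — not segmentation
accuracy on real livers, where published DICE against manual
delineation was 0.82 (high-AF) and 0.42 (low-AF), the latter limited by
a transitional zone the phantom does not reproduce.

## Problem sizes and numerical choices

The end-to-end recovery experiment uses the study's train/test design
at 64×256×256 voxels (20 µm isotropic): train on five annotated slices
(300 labeled pixels per class each) from two phantoms, predict an
independent third, and require DICE ≥ 0.8 for high-AF and ≥ 0.7 for
lumen; noise-degradation monotonicity (5% → 10% → 20%) is assessed on a
central 24-slice sub-stack of the same test phantom. The packaged liver
demo runs the identical chain at 32×128×128/10 µm with a factor-2
downsample so a full reproducible run (including written volumes)
completes in about a minute. These sizes are the package's own
demonstration scale; all operations stream slice-wise and scale to
full acquisitions.

Other conventions: axis order is (z, y, x) with 1-based R indexing;
integer TIFFs round-trip bit-exactly while float stacks are stored as
scaled 32-bit float (scale in the JSON sidecar, round trip within
float32 precision); constant inputs to `normalize_histogram()` return
zeros with a warning; a flat profile has no defined rise distance and
errors; two empty masks have DICE 1 with a warning; argmax ties resolve
to the first class in declared order.

## A worked example

```{r example, eval = FALSE}
library(afspectra)

out <- run_liver_demo(seed = 1, out_dir = "liver_run")
out$dice
#>        class      dice flagged     macro
#> 1 background 0.9707833   FALSE 0.9073663
#> 2      lumen 0.8003857   FALSE 0.9073663
#> 3     low_AF 0.9274389   FALSE 0.9073663
#> 4    high_AF 0.9308573   FALSE 0.9073663
```

The run directory contains `config.yaml` (the effective configuration),
`log.txt` (package version, config hash, and every interpretation flag
used), `tables/` (DICE, signatures, sharpness, the ERD profile) and
`volumes/` (raw and background-subtracted probability maps, predicted
and true labels). Two runs with the same seed are byte-identical.

## Known limitations

* The phantom's lumen and background share one intensity, so lumen is
  recognized purely from spatial context; very large vessels touching
  the organ border can be confused with background.
* The sharpness statistic is defined per slice; anisotropic blur along
  z is invisible to it.
* Histogram "normalization" and the sharpness contract are
  interpretations of underspecified descriptions; both are flagged in
  logs and here.
* `read_stack()` accepts plain multipage TIFF from any source, but
  rich OME-XML metadata is not parsed; voxel size travels in the JSON
  sidecar.
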