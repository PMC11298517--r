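# afspectra

Autofluorescence spectral analysis and trainable segmentation for
multi-channel light-sheet microscopy volumes of optically cleared,
**unstained** tissue.

Cleared tissue imaged by light-sheet fluorescence microscopy (LSFM)
emits intrinsic autofluorescence (AF) that differs by anatomical region
and excitation wavelength (405–785 nm). Instead of suppressing this
signal, the pipeline exploits it: per-region spectral signatures
characterize tissue label-free, digital subtraction of histogram-
normalized channels enhances structures with divergent spectra, and a
trainable pixel classifier segments unstained liver from its 785 nm AF
pattern alone — including ~1 mm percutaneous biopsy cores. The package
is aimed at microscopy and image-analysis groups who want these
quantification steps as tested, scriptable R functions rather than an
interactive toolchain.

## What it computes

* **Acquisition conditioning** — bilateral illumination fusion by
  unclipped digital addition (`fuse_bilateral`), trilinear block-average
  downsampling, e.g. 5 µm → 20 µm (`downsample_trilinear`), exposure and
  percentile histogram normalization.
* **Edge-Rise-Distance (ERD)** — intensity profiles along a line across
  a tissue boundary, replicate aggregation with a t-based 95% CI, and
  the 10–90% rise distance: for a Gaussian-blurred edge of width σ,
  d₁₀₋₉₀ = 2·z₀.₉·σ ≈ 2.5631 σ.
* **Spectral signatures** — region × channel matrices of background-
  corrected mean AF, normalized per channel (`region_signature`).
* **Virtual channels** — digital subtraction (e.g. 405−640 nm) and its
  inversion.
* **Sharpness** — the standard deviation of the Fourier power spectrum
  (spectral bandwidth of the Hann-windowed, energy-normalized, DC-free
  spectrum); decreases strictly under blur, invariant to affine
  intensity rescaling.
* **Segmentation** — WEKA-style trainable pixel classification: a
  42-feature multiscale bank (Gaussian ladder σ ∈ {0,1,2,4,8,16},
  gradient magnitude, Hessian eigenvalues, differences of Gaussians,
  membrane projections; patch 19, thickness 1) feeding a 200-tree
  probability random forest; probability maps postprocessed by
  background subtraction, P′(k) = max(P(k) − P(bg), 0) with the
  background map inverted; evaluation by per-class DICE,
  2|A∩B|/(|A|+|B|).
* **Synthetic phantoms** — liver volumes with zonation-like high/low AF
  parenchyma, dark vessel lumina, depth attenuation, one-sided
  illumination shading and signal-proportional noise, plus 1 mm biopsy
  cylinders and analytic blurred-edge fixtures, all with ground-truth
  labels and deterministic seeds.

Stacks are multipage TIFF (integer data bit-exact, float as scaled
32-bit) with a JSON sidecar for voxel size and channel metadata; channel
configs are YAML/JSON (five lasers, filters 525/50–845/55, 104 ms
exposure, 1040 ms at 785 nm).

## Worked example

The liver demo reproduces the whole workflow on synthetic data: three
phantoms are generated; the classifier is trained on five sparsely
annotated slices from each of the first two (785 nm channel); the
independent third phantom is predicted and scored.

```r
library(afspectra)
out <- run_liver_demo(seed = 1, out_dir = "liver_run")
out$dice
#>        class      dice flagged     macro
#> 1 background 0.9707833   FALSE 0.9073663
#> 2      lumen 0.8003857   FALSE 0.9073663
#> 3     low_AF 0.9274389   FALSE 0.9073663
#> 4    high_AF 0.9308573   FALSE 0.9073663
```

DICE near 1 for the two parenchymal zones means the forest recovered the
phantom's zonation from the 785 nm texture; lumen (0.80) is hardest
because vessel voxels share the background intensity and are recognized
from spatial context only. The run directory holds `config.yaml`,
`log.txt`, `tables/` (DICE, signatures, per-channel sharpness, the ERD
profile with CI) and `volumes/` (probability maps before/after
background subtraction, predicted and true labels). The signature table
in the same run ranks 785 nm brightest in parenchyma, and
`run_biopsy_demo()` applies the trained model to a 1 mm biopsy-core
phantom, reporting the measured core diameter alongside the same
metrics.

A thin CLI mirrors the functions
(`inst/exec/afspectra simulate|fuse|downsample|erd|signature|subtract|
sharpness|dice|segment-*|demo-*`).

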