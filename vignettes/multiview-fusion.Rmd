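---
title: "Multi-view fusion of orthogonal light-sheet stacks: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view fusion of orthogonal light-sheet stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthofuse)
```

## The imaging model

A light-sheet microscope optically sections a (cleared) specimen with a
thin sheet of excitation light and detects fluorescence perpendicular to
it. The in-plane (lateral) resolution is set by the detection objective;
the axial resolution is set by the sheet thickness and is typically
several-fold worse. A volume recorded this way is therefore convolved
with a strongly anisotropic PSF — sharp in (y, x), elongated in z.

If the specimen is recorded a second time after a ~90° tilt, the second
stack carries its elongation along a different axis of the specimen.
The two views contain complementary frequency content: spatial
frequencies attenuated by the axial blur of one view survive in the
other. Fusion exploits this complementarity.

## The fusion procedure

`fuse_views()` runs the following deterministic pipeline on two
co-registered stacks:

1. **Mutual masking** (`mutual_mask`). A binary mask is thresholded from
   stack I1 and multiplied onto I2, and vice versa, removing the
   non-overlapping parts that only one camera saw. The default threshold
   is Otsu's method on each stack's 256-bin histogram, with a fixed-value
   override (`fusion_config(mask_threshold = )`); the choice matters
   little for well-separated foreground, but a fixed threshold of 0 is
   the right setting for synthetic data with mathematically zero
   background.
2. **Percentile normalization** (`normalize_percentile`). Each masked
   view is divided by the 95th percentile of its *positive* voxels, so
   brightness differences between the recordings (laser power, detection
   path) cancel. Computing the percentile over masked-in voxels only
   keeps the zeroed background majority — often >90% of the volume —
   from collapsing the percentile to 0. The percentile (default 95) is
   preferred over the maximum because a single hot voxel would otherwise
   set the scale for the whole volume.
3. **Spectral decomposition** (`spectral_decompose`). The unnormalized
   forward 3D DFT of each view, stored as magnitude
   `M = sqrt(Re² + Im²)` and phase `φ = atan2(Im, Re)`. The phase is the
   four-quadrant angle: a principal-branch `arctan(Im/Re)` loses the
   quadrant and cannot represent the complex sum below.
4. **Combination** (`combine_spectra`). Per frequency,
   `M_comb = max(M₁, M₂)` — the view with the larger magnitude is the one
   that resolved this frequency more sharply — and
   `φ_comb = arg(F₁ + F₂)`, the phase of the complex sum, which blends
   the two views' positional information with magnitude weighting.
5. **Recomposition** (`recompose`). `M_comb·exp(i φ_comb)` is
   inverse-transformed; the imaginary residual is discarded and small
   negative ringing excursions are clamped to zero.

Both stacks are zero-padded to a common even shape before the transform
and the fused volume is cropped back afterwards; all arithmetic is in
double precision, and quantization happens only in the optional final
`rescale_to_uint16()`.

### Why this preserves a real image

The DFT of a real volume is Hermitian-symmetric: `F(-k) = conj(F(k))`.
Both combination rules respect that symmetry — `max` of two even
magnitude fields is even, and `arg(F₁+F₂)` of two Hermitian fields is
odd — so the combined spectrum is again Hermitian and its inverse
transform is real to machine precision. The package checks this rather
than assuming it: `recompose()` errors if the imaginary residual exceeds
`1e-4` of the peak, and `imag_residual()` exposes the number directly.

### The zero-sum tie-break

When `F₁ = -F₂` at some frequency the sum vanishes and its phase is
undefined. The package defines `φ_comb = 0` there (threshold:
`|F₁+F₂| ≤ 1e-9 (M₁+M₂)`), keeping `M_comb = max(M₁, M₂)`. Any fixed
convention works: the cancellation condition is itself symmetric under
frequency negation, so Hermitian symmetry survives. The case is
measure-zero for real data but exercised explicitly in the tests.

## Registration

The tilted stack is brought onto the reference grid by `register_rigid`,
replacing an interactive alignment step with a reproducible optimizer:

* **Metric**: normalized cross-correlation. Both views image the same
  fluorophore distribution, so a mono-modal metric suffices.
* **Search**: a 3-level coarse-to-fine pyramid (block-mean downsampling
  by 4, 2, 1) with Nelder-Mead over 6 parameters (ZYX Euler angles in
  degrees, translation in µm) composed onto the tilt initialization,
  followed by cyclic 1D line searches (window ±0.5 then ±0.1) at full
  resolution. Nelder-Mead alone reliably stalls a degree or two short on
  the flat NCC plateau near the optimum; the line searches close that
  gap. The whole search is deterministic — fixed schedule, no random
  restarts.
* **Coordinates**: transforms act in physical µm space about an explicit
  pivot, so anisotropic voxels are handled correctly; voxel centers sit
  at `index × voxel_size` with 0-based indices.
* **Interpolation**: trilinear (Rcpp), for the registration metric and
  the final resampling alike; out-of-domain voxels are 0, consistent
  with downstream masking. Exact multiples of 90° about a principal axis
  reduce to index permutations, and `rot90_stack()` provides that exact
  path both as a generator and as an oracle for `resample()`.

On synthetic pairs (blob phantoms re-rendered at exactly transformed
positions, additive noise at SNR 10) the recovery error is ≤ 0.02 voxel
for a (3, −2, 5)-voxel shift and ≤ 0.12° for a 92° rotation initialized
at 90° — the acceptance script recomputes both. A caveat discovered while
building the tests: generating the moving volume by *resampling* the
fixed one creates a spurious metric optimum at exact-lattice rotations
(where the second interpolation vanishes), biasing recovered angles by
~2°. Ground-truth pairs for registration experiments should therefore be
rendered analytically, as `transform_phantom()` + `render_phantom()` do.

## Destriping

Stripe artifacts from absorbing structures along the illumination path
run along the illumination axis: nearly constant along it, oscillating
across it. In each z-slice's 2D spectrum that energy concentrates on the
line of zero frequency along the stripe axis. `destripe_fft()`
attenuates a Gaussian-profile band around that line:

* `notch_sigma` (default **0.01 cycles/voxel**): the band's Gaussian
  width. Chosen by leakage analysis: at 0.01 the suppressed band spans
  roughly ±2 frequency bins of a 64-wide slice, which removes a pure
  stripe line completely while deleting only ~0.2% of the RMS of
  broadband (stripe-free) texture; doubling it roughly doubles the
  leakage.
* `protect_dc_radius` (default 0.02 cycles/voxel): a low-frequency disk
  left untouched, so the slice mean and coarse shading are exactly
  preserved.
* `strength` (default 1): fractional attenuation of the band.

Filtering is per 2D slice rather than fully 3D — stripes are an in-plane
artifact of each recorded plane — and the Gaussian profile avoids the
ringing a hard notch would cause.

## Post-processing

`adaptive_equalize()` (contrast-limited adaptive histogram equalization,
per slice, 256 bins; the backend requires at least a 2×2 tile grid) and
`unsharp_mask()` (`in + amount·(in − blur(in, σ))`). The default pipeline
order is destripe → fuse → equalize → unsharp: destriping before fusion
keeps stripe energy from winning magnitude comparisons, and contrast
operations come last because they are nonlinear in intensity. Blind
deconvolution is deliberately not implemented; the pipeline configuration
keeps stage toggles so one can be inserted externally.

Two boundary policies exist for the shared Gaussian blur: zero padding
(conserves interior mass — used by the acquisition simulator, where the
background is truly dark) and edge renormalization (preserves constants —
used by unsharp masking, where a flat image must stay flat).

## The synthetic acquisition simulator

`simulate_view_pair()` emulates the statistical structure the fusion
assumes, not the optics:

* **Phantoms**: point lattices (`point_grid_phantom`), random blob
  clouds (`random_blob_phantom`), filaments and shells — sparse bright
  structures on dark background, like labelled neurons in a cleared fly.
  Point/filament mass is deposited with trilinear sub-voxel spreading.
* **PSF**: separable Gaussian, `sigma_lateral` (default 1.2 voxels) on
  the in-plane axes and `sigma_axial` (default 4.0) on the detection
  axis — an axial/lateral ratio of ~3.3, within the range seen in
  light-sheet recordings. A parametric Gaussian is analytic (closed-form
  FWHM `2√(2 ln 2) σ`), which is what makes the resolution claims
  testable.
* **Geometry**: view 2 is the ground truth rotated by an exact 90° index
  permutation before blurring, so both "cameras" blur along their own z
  while the blurs are orthogonal in the common frame, and the returned
  ground-truth transform is exact by construction.
* **Noise**: Poisson counts at a configurable photons-per-intensity
  scale, plus additive Gaussian read noise. **Stripes**: multiplicative
  sinusoidal modulation (shadowing-like). All randomness flows through
  one explicit seed and leaves the caller's RNG state untouched.

What the simulator does *not* model: wave-optical sheet propagation,
scattering, refraction, depth-dependent PSF variation, non-rigid sample
motion. Passing tests therefore demonstrate that the algorithmic chain is
correct and self-consistent under the stated acquisition model — not that
registration or fusion are robust to optical effects the model omits.

## Numerical choices and degenerate inputs

* FFTs are unnormalized forward / `1/N` inverse (base R convention).
* `fuse_views(I, I)` reproduces `I` up to the normalization gain to
  machine precision; fusion is symmetric in its arguments.
* Constant volumes: rejected by registration ("no registrable content");
  rescaling a constant volume warns and returns zeros; CLAHE and
  destriping pass constants through unchanged.
* Disjoint view supports raise "no overlap" rather than silently fusing
  background.
* `fwhm()` uses the profile minimum as baseline (background offsets do
  not bias widths) and linear interpolation at the half-height
  crossings; profiles whose maximum sits on the boundary, or that never
  fall below half height, are rejected ("no peak").
* USAF-1951: bar width = `500 / 2^(group + (element−1)/6)` µm — half the
  line-pair spacing, the convention under which group 7 element 6 is
  2.19 µm.

## Problem sizes

The shipped experiments use sizes chosen to exercise the claims well
inside a laptop budget: the isotropy experiment runs on a 96³ point grid
(fused anisotropy ratio ≈ 1.11 vs ≈ 3.25 for a single view), fusion
invariants on 32³–64³ volumes, and registration recovery on 48³ blob
phantoms at SNR 10 over five seeds. All numbers quoted in this vignette
are recomputed by the test suite and `scripts/acceptance.R`, not stored.

## Known limitations

* Exactly two views; weighted or more-than-two-view spectral blending is
  out of scope.
* Rigid registration only — no affine or deformable model, and no
  bead-based multi-view registration.
* The magnitude-max rule assumes comparable noise floors in both views
  after percentile normalization; a much noisier view can win magnitude
  comparisons at high frequencies and inject its noise into the fusion.
* Per-slice destriping assumes stripes are in-plane; oblique 3D stripe
  patterns would need a 3D notch.
* TIFF voxel-size tags are not written (the underlying TIFF binding does
  not expose resolution tags); spacing travels in the `volume_stack`
  object and as a CLI argument.
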