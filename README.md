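# orthofuse

Fourier-domain fusion of orthogonally recorded light-sheet microscopy
stacks, in R.

## The problem

Light-sheet (and confocal) volumes are anisotropic: resolution along the
detection axis is limited by the light-sheet thickness and the detection
PSF, and is typically several-fold worse than the lateral resolution. If
the same cleared specimen is recorded twice, with the second view tilted
by ~90°, each view is sharp exactly where the other is blurred. This
package combines such a pair into a single volume with near-isotropic
resolution, and provides the surrounding machinery a microscopist needs:
rigid registration of the tilted view, FFT destriping, post-processing
(CLAHE, unsharp masking), resolution/ROI quantification, and a synthetic
acquisition simulator so everything can be validated without microscope
data.

## The method

Both stacks are brought onto a common grid (tilt-initialized rigid
registration maximizing normalized cross-correlation, then trilinear
resampling into virtual slices coplanar with the reference stack). The
non-overlapping parts are removed by mutual masking: a binary mask
thresholded from stack *I₁* multiplies *I₂*, and vice versa. Each masked
view is normalized to its 95th intensity percentile, and both are
transformed with a 3D FFT. Writing each coefficient in polar form,

    M(F) = sqrt(Re²(F) + Im²(F)),   φ(F) = atan2(Im(F), Re(F)),

the views are merged frequency by frequency, keeping the magnitude of
whichever view resolved that frequency more sharply and the phase of the
complex sum:

    M_comb = max(M₁, M₂),   φ_comb = arg(F₁ + F₂).

The combined spectrum `Re_comb = M_comb·cos(φ_comb)`,
`Im_comb = M_comb·sin(φ_comb)` is inverse-transformed, rescaled and
written back as a 16-bit TIFF. Because the frequencies blurred away in
one view survive in the other, a point source that is 3–4× elongated in
each single view comes back nearly spherical after fusion.

## Worked example

```r
library(orthofuse)
run_demo(seed = 1, dim = 64)
```

simulates a 64³ point-grid phantom, images it from two orthogonal
directions with an anisotropic PSF (σ_lateral = 1.2, σ_axial = 4 voxels,
shot + read noise), fuses the pair and prints:

```
single view FWHM (z, y, x): 6.16, 1.92, 1.72 voxels (ratio 3.59)
fused       FWHM (z, y, x): 2.34, 2.39, 2.74 voxels (ratio 1.17)
```

The first line is one raw view: the point-source width along the
detection axis (z) is ~3.6× the lateral width. After fusion the three
widths agree to within ~17% — the anisotropy is repaired, and no axis is
blurrier than the single-view lateral resolution by more than a small
factor. The fused stack, the exact view-to-view transform and a JSON run
report are written to the output directory.

The same pipeline is scriptable from a shell via
`inst/cli/orthofuse.R` (subcommands `simulate`, `register`, `destripe`,
`fuse`, `postprocess`, `score-usaf`, `roi-stats`, `demo`, `run`), e.g.

```sh
Rscript inst/cli/orthofuse.R score-usaf --group 7 --element 6
# 2.19
```

— the bar width in µm of USAF-1951 group 7, element 6, the finest
element resolvable through a well-cleared adult fly.

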