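#' Fusion configuration
#'
#' Collects the tunable knobs of [fuse_views()].
#'
#' @param norm_percentile percentile (0–100] used to normalize each masked
#'   view before the spectral combination; 95 by default, so brightness
#'   differences between views cancel without letting single hot voxels
#'   dictate the scale.
#' @param mask_threshold `"otsu"` for an automatic intensity threshold per
#'   view, or a fixed numeric value applied to both.
#' @param pad_to_even zero-pad each axis to the next even length before
#'   the 3D FFT (padding is cropped after recomposition).
#' @param rescale `NULL` to return the fused volume in floating point, or
#'   a length-2 percentile window passed to [rescale_to_uint16()].
#'
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(norm_percentile = 95, mask_threshold = "otsu",
                          pad_to_even = TRUE, rescale = NULL) {
  if (!is_scalar_number(norm_percentile) ||
      norm_percentile <= 0 || norm_percentile > 100) {
    stopf("norm_percentile must be in (0, 100]")
  }
  if (!(identical(mask_threshold, "otsu") || is_scalar_number(mask_threshold))) {
    stopf("mask_threshold must be \"otsu\" or a fixed numeric value")
  }
  structure(list(norm_percentile = norm_percentile,
                 mask_threshold = mask_threshold,
                 pad_to_even = isTRUE(pad_to_even),
                 rescale = rescale),
            class = "fusion_config")
}

## binary foreground mask of one view; Otsu runs on a 256-bin histogram
## of the stack's own intensity range
binary_mask <- function(stack, threshold = "otsu") {
  x <- stack$data
  if (identical(threshold, "otsu")) {
    rng <- range(x)
    if (rng[2L] <= rng[1L]) return(array(FALSE, dim(x)))
    thr <- EBImage::otsu(EBImage::Image(x), range = rng, levels = 256L)
  } else {
    thr <- threshold
  }
  x > thr
}

#' Mutual masking of two co-registered views
#'
#' Removes the non-overlapping parts of two registered stacks: a binary
#' mask is generated from the first stack by thresholding its intensities
#' and multiplied onto the second; a second mask obtained the same way
#' from the second stack is multiplied onto the first. After this step
#' both views are supported only where both cameras saw signal.
#'
#' @param i1,i2 [volume_stack()] objects on the same grid (`i2` already
#'   resampled into `i1`'s frame).
#' @param threshold `"otsu"` or a fixed numeric threshold.
#' @return A list `(i1, i2)` of masked [volume_stack()]s.
#' @export
mutual_mask <- function(i1, i2, threshold = "otsu") {
  stopifnot(inherits(i1, "volume_stack"), inherits(i2, "volume_stack"))
  if (!all(dim(i1$data) == dim(i2$data))) stopf("stacks must share a grid")
  m1 <- binary_mask(i1, threshold)
  m2 <- binary_mask(i2, threshold)
  out1 <- i1$data * m2
  out2 <- i2$data * m1
  if (!any(out1 > 0) || !any(out2 > 0)) {
    stopf("no overlap between the masked views")
  }
  list(i1 = update_data(i1, out1), i2 = update_data(i2, out2))
}

#' Normalize a stack to an intensity percentile
#'
#' Divides the stack by the `p`-th percentile of its positive voxels, so
#' that percentile maps to 1.0. Computing the percentile over positive
#' (masked-in) voxels only keeps the zeroed background majority from
#' dominating the statistic. Corrects brightness differences between the
#' two views before they are compared frequency by frequency.
#'
#' @param stack a [volume_stack()] with at least one positive voxel.
#' @param p percentile in (0, 100].
#' @return The normalized [volume_stack()].
#' @export
normalize_percentile <- function(stack, p = 95) {
  stopifnot(inherits(stack, "volume_stack"))
  pos <- stack$data[stack$data > 0]
  if (length(pos) == 0L) stopf("all-zero stack cannot be normalized")
  q <- stats::quantile(pos, p / 100, names = FALSE, type = 7)
  update_data(stack, stack$data / q)
}

#' Spectral decomposition of a volume
#'
#' Applies the unnormalized forward 3D discrete Fourier transform and
#' stores each coefficient in polar form: `magnitude = sqrt(Re^2 + Im^2)`
#' and `phase = atan2(Im, Re)` (four-quadrant angle in `(-pi, pi]`).
#' For a real input the result is Hermitian-symmetric: magnitude even and
#' phase odd under frequency-index negation.
#'
#' @param stack a [volume_stack()] (or bare 3D array) with finite values.
#' @return An object of class `spectral_volume` with fields `magnitude`,
#'   `phase`, `shape`, `voxel_size`.
#' @seealso [combine_spectra()], [recompose()]
#' @export
spectral_decompose <- function(stack) {
  if (inherits(stack, "volume_stack")) {
    x <- stack$data; vox <- stack$voxel_size
  } else {
    x <- stack; vox <- c(1, 1, 1)
    if (!is.array(x) || length(dim(x)) != 3L) stopf("need a 3D array")
  }
  if (any(!is.finite(x))) stopf("non-finite values in input")
  F <- stats::fft(x)
  structure(list(magnitude = Mod(F), phase = Arg(F), shape = dim(x),
                 voxel_size = vox),
            class = "spectral_volume")
}

#' Combine two spectra by magnitude maximum and phase of the complex sum
#'
#' The core of the multi-view combination. Per frequency, the higher
#' magnitude of the two views is kept — the view that resolved this
#' frequency more sharply wins — while the phase is taken from the sum of
#' the two complex coefficients `F1 + F2`, which averages the views'
#' positional information with magnitude weighting.
#'
#' When `F1 + F2` vanishes (the coefficients cancel exactly) the phase is
#' defined as 0; the condition is symmetric under frequency negation, so
#' any fixed convention preserves Hermitian symmetry.
#'
#' @param s1,s2 `spectral_volume` objects of identical shape.
#' @param tol cancellation threshold: the phase is set to 0 where
#'   `|F1 + F2| <= tol * (M1 + M2)`, i.e. where the two coefficients
#'   annihilate each other to floating-point precision.
#' @return A `spectral_volume`.
#' @export
combine_spectra <- function(s1, s2, tol = 1e-9) {
  stopifnot(inherits(s1, "spectral_volume"), inherits(s2, "spectral_volume"))
  if (!all(s1$shape == s2$shape)) stopf("shape mismatch between spectra")
  F1 <- complex(modulus = s1$magnitude, argument = s1$phase)
  F2 <- complex(modulus = s2$magnitude, argument = s2$phase)
  S <- F1 + F2
  mag <- pmax(s1$magnitude, s2$magnitude)
  ph <- Arg(S)
  dead <- Mod(S) <= tol * (s1$magnitude + s2$magnitude)
  ph[dead] <- 0
  dim(mag) <- s1$shape
  dim(ph) <- s1$shape
  structure(list(magnitude = mag, phase = ph, shape = s1$shape,
                 voxel_size = s1$voxel_size),
            class = "spectral_volume")
}

#' Recompose a spectral volume into the spatial domain
#'
#' Rebuilds the complex spectrum as `Re = M cos(phi)`, `Im = M sin(phi)`,
#' applies the inverse 3D transform (normalized by the voxel count), drops
#' the imaginary residual and clamps negatives to 0. A combined spectrum
#' of two real volumes is Hermitian-symmetric, so the residual is at
#' numerical-noise level; a large residual signals a broken-symmetry
#' input and raises an error.
#'
#' @param s a `spectral_volume`.
#' @param max_imag_frac error threshold on `max|Im| / max|Re|` of the
#'   inverse transform.
#' @param clamp_negatives clamp small negative excursions (FFT ringing)
#'   to 0. Disable to inspect the raw inverse transform, e.g. when
#'   checking that the fused volume's spectrum carries exactly the
#'   combined magnitudes.
#' @return A [volume_stack()] (negatives kept as an attribute-free raw
#'   array only when `clamp_negatives = FALSE`, returned as a plain 3D
#'   array in that case).
#' @export
recompose <- function(s, max_imag_frac = 1e-4, clamp_negatives = TRUE) {
  stopifnot(inherits(s, "spectral_volume"))
  F <- complex(modulus = s$magnitude, argument = s$phase)
  dim(F) <- s$shape
  x <- stats::fft(F, inverse = TRUE) / prod(s$shape)
  peak <- max(Mod(x))
  if (peak > 0 && max(abs(Im(x))) > max_imag_frac * peak) {
    stopf("imaginary residual %.3g of peak: spectrum is not Hermitian-symmetric",
          max(abs(Im(x))) / peak)
  }
  out <- Re(x)
  if (!clamp_negatives) return(out)
  out[out < 0] <- 0
  volume_stack(out, voxel_size = s$voxel_size)
}

#' Imaginary residual of a spectral volume's inverse transform
#'
#' Returns `max|Im| / max|modulus|` of the inverse 3D transform — a
#' direct measure of how far the spectrum is from Hermitian symmetry
#' (it is 0, up to floating-point noise, for any spectrum derived from
#' real volumes, including combined ones).
#'
#' @param s a `spectral_volume`.
#' @return A non-negative scalar.
#' @export
imag_residual <- function(s) {
  stopifnot(inherits(s, "spectral_volume"))
  F <- complex(modulus = s$magnitude, argument = s$phase)
  dim(F) <- s$shape
  x <- stats::fft(F, inverse = TRUE) / prod(s$shape)
  max(abs(Im(x))) / max(Mod(x))
}

pad_even <- function(x) {
  d <- dim(x)
  nd <- d + d %% 2L
  if (all(nd == d)) return(x)
  out <- array(0, nd)
  out[seq_len(d[1L]), seq_len(d[2L]), seq_len(d[3L])] <- x
  out
}

#' Fuse two co-registered views in the Fourier domain
#'
#' The full multi-view combining pipeline: mutual masking, percentile
#' normalization of both views, zero-padding to a common even shape, 3D
#' spectral decomposition, magnitude-max / phase-sum combination,
#' inverse transform, cropping, and (optionally) 16-bit rescaling. The
#' operation is deterministic and symmetric in its two inputs.
#'
#' @param i1 the reference view, a [volume_stack()].
#' @param i2_registered the tilted view already resampled onto `i1`'s
#'   grid (see [register_rigid()] and [resample()]).
#' @param config a [fusion_config()].
#' @return The fused [volume_stack()]; floating point unless
#'   `config$rescale` is set.
#' @examples
#' \donttest{
#' ph <- point_grid_phantom(c(48, 48, 48), spacing = 16)
#' sim <- simulate_view_pair(ph, psf_model(1.2, 4), tilt_axis = "y", seed = 1)
#' i2r <- resample(sim$view2, sim$transform, sim$view1)
#' fused <- fuse_views(sim$view1, i2r, fusion_config())
#' }
#' @export
fuse_views <- function(i1, i2_registered, config = fusion_config()) {
  stopifnot(inherits(config, "fusion_config"))
  masked <- mutual_mask(i1, i2_registered, config$mask_threshold)
  n1 <- normalize_percentile(masked$i1, config$norm_percentile)
  n2 <- normalize_percentile(masked$i2, config$norm_percentile)
  d <- dim(n1$data)
  a1 <- if (config$pad_to_even) pad_even(n1$data) else n1$data
  a2 <- if (config$pad_to_even) pad_even(n2$data) else n2$data
  s1 <- spectral_decompose(volume_stack(a1, voxel_size = i1$voxel_size))
  s2 <- spectral_decompose(volume_stack(a2, voxel_size = i1$voxel_size))
  fusedarr <- recompose(combine_spectra(s1, s2))$data
  fusedarr <- fusedarr[seq_len(d[1L]), seq_len(d[2L]), seq_len(d[3L]),
                       drop = FALSE]
  out <- volume_stack(fusedarr, voxel_size = i1$voxel_size,
                      view_id = paste0(i1$view_id, "+", i2_registered$view_id))
  if (!is.null(config$rescale)) {
    out <- rescale_to_uint16(out, config$rescale[1L], config$rescale[2L])
  }
  out
}
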