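## --- separable Gaussian blur -------------------------------------------

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

## 1D Gaussian convolution along one axis of a 3D array, implemented as
## a banded-matrix product so the inner loop is BLAS. Boundary handling:
## "zero" pads with zeros (interior mass conserved exactly — the right
## choice for simulating acquisitions of objects on dark background);
## "renorm" renormalizes the truncated kernel at the edges (constants
## are preserved exactly — the right choice for image filters).
blur_axis <- function(a, axis, sigma, boundary = "zero") {
  if (sigma <= 0) return(a)
  d <- dim(a)
  n <- d[axis]
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1L & j <= n
    K[i, j[ok]] <- k[ok]
  }
  if (boundary == "renorm") K <- K / rowSums(K)
  perm <- c(axis, setdiff(1:3, axis))
  b <- aperm(a, perm)
  pd <- dim(b)
  dim(b) <- c(n, prod(pd[-1L]))
  b <- K %*% b
  dim(b) <- pd
  aperm(b, order(perm))
}

#' Separable anisotropic Gaussian blur of a volume
#'
#' @param stack a [volume_stack()] or 3D array.
#' @param sigma standard deviation in voxels per axis `(z, y, x)`;
#'   a scalar is applied isotropically. Zero disables blurring along an
#'   axis.
#' @param boundary `"zero"` (zero padding; conserves interior mass) or
#'   `"renorm"` (edge-renormalized kernel; preserves constants).
#' @return Same type as the input.
#' @export
gaussian_blur_3d <- function(stack, sigma, boundary = c("zero", "renorm")) {
  boundary <- match.arg(boundary)
  sigma <- rep_len(as.numeric(sigma), 3L)
  if (any(sigma < 0)) stopf("sigma must be non-negative")
  a <- if (inherits(stack, "volume_stack")) stack$data else stack
  for (ax in 1:3) a <- blur_axis(a, ax, sigma[ax], boundary)
  if (inherits(stack, "volume_stack")) update_data(stack, a, clamp = TRUE) else a
}

## --- FFT destriping ----------------------------------------------------

#' Destriping parameters
#'
#' Stripe artifacts in light-sheet recordings run along the illumination
#' direction: the pattern is (nearly) constant along `stripe_axis` and
#' oscillates perpendicular to it, so in each slice's 2D spectrum its
#' energy concentrates on the line of zero frequency along the stripe
#' axis. [destripe_fft()] attenuates a narrow Gaussian-profile band
#' around that line, sparing a low-frequency disk so the image mean and
#' coarse structure pass through untouched.
#'
#' @param stripe_axis `"y"` or `"x"` — the in-plane axis the stripes run
#'   along.
#' @param notch_sigma Gaussian width of the suppression band, cycles per
#'   voxel along the stripe axis. The default 0.01 removes the
#'   stripe-frequency line while leaving broadband texture essentially
#'   unchanged.
#' @param strength suppression factor in `[0, 1]`; 1 removes the band
#'   completely.
#' @param protect_dc_radius radius (cycles/voxel) of the untouched
#'   low-frequency disk.
#' @return An object of class `destripe_params`.
#' @export
destripe_params <- function(stripe_axis = "y", notch_sigma = 0.01,
                            strength = 1, protect_dc_radius = 0.02) {
  if (!stripe_axis %in% c("y", "x")) {
    stopf("stripe_axis must be 'y' or 'x' (filtering is per z-slice)")
  }
  if (!(is_scalar_number(notch_sigma) && notch_sigma > 0)) {
    stopf("notch_sigma must be > 0")
  }
  if (!(is_scalar_number(strength) && strength >= 0 && strength <= 1)) {
    stopf("strength must be in [0, 1]")
  }
  structure(list(stripe_axis = stripe_axis, notch_sigma = notch_sigma,
                 strength = strength, protect_dc_radius = protect_dc_radius),
            class = "destripe_params")
}

fft_freqs <- function(n) {
  k <- c(0:(n - n %/% 2 - 1), -(n %/% 2):-1)
  k / n
}

#' Remove stripe artifacts with a Fourier-domain notch filter
#'
#' Each z-slice is transformed with a 2D FFT; frequencies within a
#' Gaussian band around zero frequency along the stripe axis are
#' attenuated by `strength`, excluding a protected low-frequency disk;
#' the slice is inverse-transformed and negatives are clamped to 0.
#'
#' @param stack a [volume_stack()] with in-plane dimensions of at least
#'   8 voxels.
#' @param params a [destripe_params()].
#' @return The filtered [volume_stack()].
#' @export
destripe_fft <- function(stack, params = destripe_params()) {
  stopifnot(inherits(stack, "volume_stack"),
            inherits(params, "destripe_params"))
  d <- dim(stack$data)
  if (any(d[2:3] < 8L)) stopf("slices must be at least 8 voxels per axis")
  fy <- fft_freqs(d[2L])
  fx <- fft_freqs(d[3L])
  f_along <- if (params$stripe_axis == "y") {
    matrix(fy, d[2L], d[3L])
  } else {
    matrix(fx, d[2L], d[3L], byrow = TRUE)
  }
  rad2 <- outer(fy^2, fx^2, `+`)
  w <- 1 - params$strength * exp(-f_along^2 / (2 * params$notch_sigma^2))
  w[rad2 < params$protect_dc_radius^2] <- 1
  out <- stack$data
  for (z in seq_len(d[1L])) {
    sl <- stats::fft(out[z, , ]) * w
    out[z, , ] <- Re(stats::fft(sl, inverse = TRUE)) / (d[2L] * d[3L])
  }
  update_data(stack, out, clamp = TRUE)
}

## --- unsharp masking ---------------------------------------------------

#' Unsharp masking
#'
#' Sharpens by adding back the difference between the image and a
#' Gaussian-blurred copy: `out = in + amount * (in - blur(in, sigma))`,
#' clamped to be non-negative.
#'
#' @param stack a [volume_stack()].
#' @param sigma blur standard deviation in voxels (> 0), applied to all
#'   three axes.
#' @param amount sharpening gain (>= 0); 0 is the identity.
#' @return The sharpened [volume_stack()].
#' @export
unsharp_mask <- function(stack, sigma = 2, amount = 0.8) {
  stopifnot(inherits(stack, "volume_stack"))
  if (!(is_scalar_number(sigma) && sigma > 0)) stopf("sigma must be > 0")
  if (!(is_scalar_number(amount) && amount >= 0)) stopf("amount must be >= 0")
  if (amount == 0) return(stack)
  blur <- gaussian_blur_3d(stack$data, sigma, boundary = "renorm")
  update_data(stack, stack$data + amount * (stack$data - blur), clamp = TRUE)
}

## --- adaptive histogram equalization -----------------------------------

#' Contrast-limited adaptive histogram equalization (per slice)
#'
#' Applies CLAHE to every z-slice independently. Intensities are first
#' scaled by the stack's nominal range (or its maximum), so the output is
#' bounded in `[0, 1]`.
#'
#' @param stack a [volume_stack()].
#' @param tile contextual-region size in voxels per block (>= 4); the
#'   number of tiles per axis is the slice extent divided by `tile`,
#'   at least 1.
#' @param clip histogram clip limit (> 0) bounding the local contrast
#'   amplification, as in standard CLAHE.
#' @return A [volume_stack()] with values in `[0, 1]`.
#' @export
adaptive_equalize <- function(stack, tile = 64, clip = 2) {
  stopifnot(inherits(stack, "volume_stack"))
  if (!(is_scalar_number(tile) && tile >= 4)) stopf("tile must be >= 4")
  if (!(is_scalar_number(clip) && clip > 0)) stopf("clip must be > 0")
  d <- dim(stack$data)
  top <- if (!is.null(stack$dtype_range)) stack$dtype_range[2L] else max(stack$data)
  if (top <= 0) top <- 1
  x <- pmin(stack$data / top, 1)
  ## the CLAHE backend needs at least a 2 x 2 grid of contextual regions
  nx <- max(2L, floor(d[2L] / tile))
  ny <- max(2L, floor(d[3L] / tile))
  out <- x
  for (z in seq_len(d[1L])) {
    sl <- x[z, , ]
    if (diff(range(sl)) == 0) { out[z, , ] <- sl; next }
    eq <- EBImage::clahe(EBImage::Image(sl), nx = nx, ny = ny,
                         bins = 256L, limit = clip, keep.range = FALSE)
    out[z, , ] <- pmin(pmax(EBImage::imageData(eq), 0), 1)
  }
  v <- update_data(stack, out)
  v$dtype_range <- c(0, 1)
  v
}
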