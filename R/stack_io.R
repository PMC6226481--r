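#' Construct a volume stack
#'
#' A `volume_stack` is the package's container for a 3D grayscale image:
#' a numeric array indexed `(z, y, x)` (z is the slice/scan axis, matching
#' multi-page TIFF page order) together with the physical voxel spacing.
#' All pipeline stages consume and produce this type and preserve the axis
#' order.
#'
#' @param data 3D numeric array indexed `(z, y, x)`; intensities must be
#'   finite and non-negative.
#' @param voxel_size numeric length-3, voxel spacing in micrometres per
#'   axis `(z, y, x)`; all entries must be positive.
#' @param view_id free-form label identifying the view (e.g. `"I1"`).
#' @param dtype_range nominal intensity range of the source data, e.g.
#'   `c(0, 65535)` for 16-bit input; `NULL` when unknown.
#'
#' @return An object of class `volume_stack` with fields `data`,
#'   `voxel_size`, `view_id`, `dtype_range`.
#' @examples
#' v <- volume_stack(array(runif(4 * 5 * 6), c(4, 5, 6)))
#' dim(v$data)
#' @export
volume_stack <- function(data, voxel_size = c(1, 1, 1), view_id = "",
                         dtype_range = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stopf("data must be a 3D array indexed (z, y, x)")
  }
  storage.mode(data) <- "double"
  if (anyNA(data) || any(!is.finite(data))) stopf("data contains non-finite values")
  if (any(data < 0)) stopf("intensities must be non-negative")
  if (any(dim(data) < 1L)) stopf("all three dimensions must be >= 1")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stopf("voxel_size must be three positive values (z, y, x) in µm")
  }
  structure(
    list(data = data, voxel_size = voxel_size,
         view_id = as.character(view_id)[1L], dtype_range = dtype_range),
    class = "volume_stack"
  )
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume_stack %s: %d x %d x %d (z,y,x), voxel %.3g x %.3g x %.3g um\n",
              if (nzchar(x$view_id)) paste0("'", x$view_id, "'") else "",
              d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume_stack <- function(x) dim(x$data)

as_volume_stack <- function(x, template = NULL) {
  if (inherits(x, "volume_stack")) return(x)
  if (!is.null(template)) {
    volume_stack(x, voxel_size = template$voxel_size, view_id = template$view_id,
                 dtype_range = template$dtype_range)
  } else {
    volume_stack(x)
  }
}

## Replace the data array, keeping metadata. Negative values are clamped
## when clamp = TRUE (filters guarantee non-negative output this way).
update_data <- function(stack, data, clamp = FALSE) {
  if (clamp) data[data < 0] <- 0
  volume_stack(data, voxel_size = stack$voxel_size, view_id = stack$view_id,
               dtype_range = stack$dtype_range)
}

#' Read a 3D grayscale TIFF stack
#'
#' Reads a single- or multi-page grayscale TIFF into a [volume_stack()],
#' one z-slice per page, in page order. Integer sample values (8- or
#' 16-bit unsigned) are preserved losslessly.
#'
#' @param path path to the TIFF file.
#' @param voxel_size voxel spacing `(z, y, x)` in micrometres. When `NULL`,
#'   an isotropic 1 micrometre spacing is assumed and a warning is issued,
#'   since downstream registration works in physical coordinates.
#' @param view_id optional label stored on the returned stack.
#'
#' @return A [volume_stack()]. `dtype_range` is set from the file's bit
#'   depth.
#' @seealso [write_stack()]
#' @export
read_stack <- function(path, voxel_size = NULL, view_id = "") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shapes <- lapply(pages, dim)
  if (any(vapply(shapes, length, 1L) != 2L)) {
    stopf("RGB/multichannel TIFF not supported; a grayscale stack is required")
  }
  if (length(unique(vapply(shapes, paste, "", collapse = "x"))) != 1L) {
    stopf("inconsistent page shapes in %s", path)
  }
  bps <- attr(pages[[1L]], "bits.per.sample") %||% 16L
  if (is.null(voxel_size)) {
    warnf("no voxel size supplied for %s; assuming isotropic 1 um", path)
    voxel_size <- c(1, 1, 1)
  }
  nz <- length(pages)
  d2 <- dim(pages[[1L]])
  arr <- array(0, c(nz, d2[1L], d2[2L]))
  for (z in seq_len(nz)) arr[z, , ] <- pages[[z]]
  volume_stack(arr, voxel_size = voxel_size, view_id = view_id,
               dtype_range = c(0, 2^bps - 1))
}

#' Write a volume stack as a multi-page 16-bit TIFF
#'
#' One page is written per z-slice. The stack must already hold integer
#' values inside the target bit depth; floating-point results are
#' converted with [rescale_to_uint16()] first.
#'
#' @param stack a [volume_stack()] with integer-valued data in
#'   `[0, 2^bits - 1]`.
#' @param path output file path.
#' @param bits bits per sample, 8 or 16 (default 16).
#'
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(inherits(stack, "volume_stack"))
  if (!bits %in% c(8L, 16L)) stopf("bits must be 8 or 16")
  x <- stack$data
  if (any(!is.finite(x))) stopf("non-finite values; cannot write")
  maxval <- 2^bits - 1
  if (any(x != round(x)) || max(x) > maxval) {
    stopf("rescale before writing: data must be integer-valued in [0, %d] (see rescale_to_uint16)",
          maxval)
  }
  nz <- dim(x)[1L]
  pages <- lapply(seq_len(nz), function(z) x[z, , ] / maxval)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits),
                  reduce = FALSE, compression = "none")
  invisible(path)
}

#' Rescale a floating-point volume to 16-bit integers
#'
#' Clips intensities to a percentile window and maps the window linearly
#' onto `[0, 65535]`, rounding to integers — the final step before a fused
#' volume is written back to disk. The default window `(0, 99.9)` keeps
#' single hot voxels from crushing the dynamic range of the bulk signal.
#'
#' @param stack a [volume_stack()].
#' @param clip_low,clip_high percentiles (0–100) bounding the window;
#'   `clip_low < clip_high`.
#'
#' @return A [volume_stack()] with integer values in `[0, 65535]` and
#'   `dtype_range = c(0, 65535)`. A constant input (zero-width window)
#'   maps to all zeros with a warning.
#' @examples
#' v <- volume_stack(array(seq(0, 1, length.out = 64), c(4, 4, 4)))
#' r <- rescale_to_uint16(v, 0, 100)
#' range(r$data)  # 0 65535
#' @export
rescale_to_uint16 <- function(stack, clip_low = 0, clip_high = 99.9) {
  stopifnot(inherits(stack, "volume_stack"))
  if (!(clip_low >= 0 && clip_low < clip_high && clip_high <= 100)) {
    stopf("need 0 <= clip_low < clip_high <= 100")
  }
  qs <- stats::quantile(stack$data, c(clip_low, clip_high) / 100,
                        names = FALSE, type = 7)
  lo <- qs[1L]; hi <- qs[2L]
  if (hi <= lo) {
    warnf("constant intensity window; output is all zeros")
    out <- array(0, dim(stack$data))
  } else {
    out <- pmin(pmax(stack$data, lo), hi)
    out <- round((out - lo) / (hi - lo) * 65535)
  }
  v <- update_data(stack, out)
  v$dtype_range <- c(0, 65535)
  v
}
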