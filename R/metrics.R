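#' Full width at half maximum of a 1D profile
#'
#' The operational resolution measure: the width of the peak at half of
#' `max - baseline`, with linear interpolation between samples. The
#' baseline is the profile minimum, so a constant background offset does
#' not bias the width, and the measure is invariant under intensity
#' scaling.
#'
#' @param profile numeric vector with an interior peak above its
#'   baseline.
#' @return Width in sample units.
#' @examples
#' x <- seq(-15, 15)
#' fwhm(exp(-x^2 / (2 * 2^2)))  # ~ 2 * sqrt(2 * log(2)) * 2 = 4.71
#' @export
fwhm <- function(profile) {
  profile <- as.numeric(profile)
  n <- length(profile)
  if (n < 3L) stopf("no peak: profile too short")
  base <- min(profile)
  peak <- which.max(profile)
  if (profile[peak] <= base) stopf("no peak: flat profile")
  if (peak == 1L || peak == n) stopf("no peak: maximum on the boundary")
  half <- base + (profile[peak] - base) / 2
  ## linear interpolation between the last sample at/above `half` and the
  ## first one below it, walking outward from the peak on each side
  left <- NA_real_
  for (i in seq(peak - 1L, 1L)) {
    if (profile[i] < half) {
      left <- i + (half - profile[i]) / (profile[i + 1L] - profile[i])
      break
    }
  }
  right <- NA_real_
  for (i in seq(peak + 1L, n)) {
    if (profile[i] < half) {
      right <- i - (half - profile[i]) / (profile[i - 1L] - profile[i])
      break
    }
  }
  if (is.na(left) || is.na(right)) {
    stopf("no peak: profile does not fall below half maximum on both sides")
  }
  right - left
}

#' Per-axis FWHM of a point source in a volume
#'
#' Locates the brightest voxel within `search_radius` of `center` and
#' measures [fwhm()] along the three axis-aligned profiles through it.
#' The three widths quantify resolution anisotropy: for a single
#' light-sheet view the detection-axis width is several-fold larger than
#' the lateral ones; after fusion of orthogonal views the three should
#' nearly agree.
#'
#' @param stack a [volume_stack()].
#' @param center voxel index `(z, y, x)` (1-based) near the point.
#' @param search_radius voxels searched around `center` for the peak.
#' @return Named numeric vector `c(z =, y =, x =)`, widths in voxels.
#' @export
point_fwhm_3d <- function(stack, center, search_radius = 3L) {
  stopifnot(inherits(stack, "volume_stack"))
  d <- dim(stack$data)
  center <- round(as.numeric(center))
  if (length(center) != 3L || any(center < 1) || any(center > d)) {
    stopf("center must be a voxel index inside the stack")
  }
  lo <- pmax(center - search_radius, 1)
  hi <- pmin(center + search_radius, d)
  sub <- stack$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  pk <- arrayInd(which.max(sub), dim(sub))[1L, ] + lo - 1L
  if (stack$data[pk[1], pk[2], pk[3]] <= min(stack$data)) {
    stopf("no peak within search radius")
  }
  c(z = fwhm(stack$data[, pk[2], pk[3]]),
    y = fwhm(stack$data[pk[1], , pk[3]]),
    x = fwhm(stack$data[pk[1], pk[2], ]))
}

#' USAF-1951 element to resolvable bar width
#'
#' The USAF-1951 chart indexes bar triplets by group and element; the
#' line-pair frequency is `2^(group + (element - 1) / 6)` line pairs per
#' millimetre, doubling per group in six geometric steps. The resolvable
#' bar width is half the line-pair spacing, `500 / frequency`
#' micrometres. Reading the finest resolved element through a cleared
#' specimen grades its transparency; group 7 element 6 corresponds to
#' 2.19 µm.
#'
#' @param group chart group, integer in -2..9.
#' @param element element within the group, integer in 1..6.
#' @return Bar width in micrometres, rounded to 2 decimals.
#' @examples
#' usaf_resolution(7, 6)  # 2.19
#' @export
usaf_resolution <- function(group, element) {
  if (!(is_scalar_number(group) && group == round(group) &&
        group >= -2 && group <= 9)) {
    stopf("group must be an integer in -2..9")
  }
  if (!(is_scalar_number(element) && element == round(element) &&
        element >= 1 && element <= 6)) {
    stopf("element must be an integer in 1..6")
  }
  freq_lp_mm <- 2^(group + (element - 1) / 6)
  round(500 / freq_lp_mm, 2)
}

#' Intensity statistics within a region of interest
#'
#' Mean, standard deviation and a brightness histogram over the ROI
#' voxels — the summary used to compare identically placed regions of
#' registered recordings (e.g. the same specimen at different time
#' points) for signal stability.
#'
#' @param stack a [volume_stack()].
#' @param roi either a logical array of the stack's dimensions, or a
#'   box `c(z0, z1, y0, y1, x0, x1)` of 1-based inclusive voxel bounds.
#' @param breaks number of histogram bins, or a vector of bin edges
#'   (passed to [graphics::hist()]).
#' @return An object of class `roi_stats`: list with `mean`, `sd`,
#'   `histogram` (`breaks`, `counts`), `n`.
#' @export
roi_stats <- function(stack, roi, breaks = 32) {
  stopifnot(inherits(stack, "volume_stack"))
  d <- dim(stack$data)
  if (is.logical(roi)) {
    if (!all(dim(roi) == d)) stopf("roi mask dimensions do not match stack")
    vals <- stack$data[roi]
  } else {
    b <- as.integer(roi)
    if (length(b) != 6L) stopf("roi box must be c(z0, z1, y0, y1, x0, x1)")
    if (any(b[c(1, 3, 5)] < 1) || any(b[c(2, 4, 6)] > d) ||
        any(b[c(1, 3, 5)] > b[c(2, 4, 6)])) {
      stopf("roi box out of bounds")
    }
    vals <- stack$data[b[1]:b[2], b[3]:b[4], b[5]:b[6]]
  }
  if (length(vals) == 0L) stopf("empty roi")
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
  s <- if (length(vals) > 1L) stats::sd(vals) else 0
  structure(list(mean = mean(vals), sd = s,
                 histogram = list(breaks = h$breaks, counts = h$counts),
                 n = length(vals)),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("roi_stats: n = %d, mean = %.4g, sd = %.4g\n",
              x$n, x$mean, x$sd))
  invisible(x)
}
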