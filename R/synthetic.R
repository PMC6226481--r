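#' Ground-truth phantom specification
#'
#' Describes a noiseless test scene — isolated puncta, neurite-like
#' filaments, or spherical shells — on a voxel grid, standing in for the
#' sparse fluorophore distributions (cell bodies, neurites) that
#' light-sheet recordings of labelled specimens contain.
#'
#' @param primitives list of primitive descriptions. Each is a list with
#'   `kind` (`"point"`, `"filament"` or `"shell"`) and:
#'   * point: `position` (length-3 µm), `intensity` (total deposited
#'     mass, a.u.);
#'   * filament: `from`, `to` (length-3 µm), `intensity` (total mass
#'     spread uniformly along the segment);
#'   * shell: `position` (center, µm), `radius` (µm), `intensity`
#'     (additive value per shell voxel), optional `thickness` (µm,
#'     default one voxel).
#' @param dim grid shape `(z, y, x)` in voxels.
#' @param voxel_size voxel spacing in µm (scalar or length 3).
#' @return An object of class `phantom`.
#' @seealso [render_phantom()], [point_grid_phantom()]
#' @export
phantom <- function(primitives, dim, voxel_size = c(1, 1, 1)) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L))
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  stopifnot(all(voxel_size > 0))
  for (p in primitives) {
    if (!is.list(p) || is.null(p$kind) ||
        !p$kind %in% c("point", "filament", "shell")) {
      stopf("each primitive needs kind 'point', 'filament' or 'shell'")
    }
  }
  structure(list(primitives = primitives, dim = dim, voxel_size = voxel_size),
            class = "phantom")
}

## trilinear mass deposit at a continuous 0-based voxel index
deposit_point <- function(arr, idx, intensity) {
  d <- dim(arr)
  if (any(idx < 0) || any(idx > d - 1)) stopf("primitive outside grid")
  i0 <- pmin(floor(idx), d - 2)
  i0 <- pmax(i0, 0)
  f <- idx - i0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- prod(ifelse(c(dz, dy, dx) == 1, f, 1 - f))
    if (w > 0) {
      at <- i0 + c(dz, dy, dx) + 1
      arr[at[1], at[2], at[3]] <- arr[at[1], at[2], at[3]] + intensity * w
    }
  }
  arr
}

#' Render a phantom into a noiseless volume
#'
#' Point and filament primitives deposit their intensity mass with
#' trilinear spreading at sub-voxel positions, so total intensity equals
#' the summed primitive intensities; shells add a fixed value to every
#' voxel within half a thickness of the spherical surface. Rendering is
#' deterministic.
#'
#' @param spec a [phantom()].
#' @return A [volume_stack()].
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom"))
  arr <- array(0, spec$dim)
  vox <- spec$voxel_size
  for (p in spec$primitives) {
    if (p$kind == "point") {
      arr <- deposit_point(arr, as.numeric(p$position) / vox, p$intensity)
    } else if (p$kind == "filament") {
      a <- as.numeric(p$from) / vox
      b <- as.numeric(p$to) / vox
      len <- sqrt(sum((b - a)^2))
      nstep <- max(2L, ceiling(len / 0.25) + 1L)
      ts <- seq(0, 1, length.out = nstep)
      for (t in ts) {
        arr <- deposit_point(arr, a + t * (b - a), p$intensity / nstep)
      }
    } else if (p$kind == "shell") {
      cen <- as.numeric(p$position)
      thick <- p$thickness %||% max(vox)
      gz <- (seq_len(spec$dim[1]) - 1) * vox[1] - cen[1]
      gy <- (seq_len(spec$dim[2]) - 1) * vox[2] - cen[2]
      gx <- (seq_len(spec$dim[3]) - 1) * vox[3] - cen[3]
      r2 <- outer(outer(gz^2, gy^2, `+`), gx^2, `+`)
      sel <- abs(sqrt(r2) - p$radius) <= thick / 2
      if (!any(sel)) stopf("primitive outside grid")
      arr[sel] <- arr[sel] + p$intensity
    }
  }
  volume_stack(arr, voxel_size = vox, view_id = "truth")
}

#' Regular grid of point sources
#'
#' Convenience phantom used throughout the tests: isolated puncta on a
#' regular lattice, far enough from the boundary that blurring and
#' rotation keep them in the interior.
#'
#' @param dim grid shape `(z, y, x)` in voxels.
#' @param spacing lattice period in voxels.
#' @param margin minimum distance from any face in voxels.
#' @param intensity mass per point.
#' @param voxel_size µm per voxel.
#' @return A [phantom()].
#' @export
point_grid_phantom <- function(dim, spacing = 24, margin = NULL,
                               intensity = 1000, voxel_size = 1) {
  dim <- as.integer(rep_len(dim, 3L))
  if (is.null(margin)) margin <- max(8, ceiling(min(dim) / 6))
  vox <- rep_len(as.numeric(voxel_size), 3L)
  pos_axis <- function(n) {
    lo <- margin; hi <- n - 1 - margin
    if (hi < lo) return((n - 1) / 2)
    seq(lo, hi, by = spacing)
  }
  zs <- pos_axis(dim[1]); ys <- pos_axis(dim[2]); xs <- pos_axis(dim[3])
  prims <- list()
  for (z in zs) for (y in ys) for (x in xs) {
    prims[[length(prims) + 1L]] <-
      list(kind = "point", position = c(z, y, x) * vox, intensity = intensity)
  }
  phantom(prims, dim, vox)
}

#' Anisotropic point-spread-function model
#'
#' The light-sheet PSF is sharp in the detection plane and elongated
#' along the detection axis (light-sheet thickness), which is the
#' anisotropy the multi-view fusion repairs. Modeled as a separable
#' Gaussian: `sigma_lateral` on the two in-plane axes, `sigma_axial`
#' (>= lateral) on the detection axis.
#'
#' @param sigma_lateral,sigma_axial standard deviations in voxels;
#'   `sigma_axial >= sigma_lateral > 0`.
#' @param detection_axis grid axis carrying the axial blur (`"z"` for a
#'   stack whose slices are detection planes).
#' @return An object of class `psf_model`.
#' @export
psf_model <- function(sigma_lateral = 1.2, sigma_axial = 4,
                      detection_axis = "z") {
  if (!(sigma_lateral > 0 && sigma_axial >= sigma_lateral)) {
    stopf("need sigma_axial >= sigma_lateral > 0")
  }
  if (!detection_axis %in% c("z", "y", "x")) stopf("invalid detection_axis")
  structure(list(sigma_lateral = sigma_lateral, sigma_axial = sigma_axial,
                 detection_axis = detection_axis),
            class = "psf_model")
}

#' Multiplicative stripe model
#'
#' Absorption along the illumination path shadows everything behind the
#' absorber, producing stripes that run along the illumination axis and
#' modulate the local intensity multiplicatively:
#' `1 + amplitude * sin(2 pi u / period + phase_offset)` where `u` is the
#' in-plane coordinate perpendicular to the stripe axis.
#'
#' @param period stripe period in voxels.
#' @param amplitude modulation depth as a fraction of local intensity
#'   (>= 0).
#' @param axis `"y"` or `"x"`: the axis the stripes run along.
#' @param phase_offset radians.
#' @return An object of class `stripe_model`.
#' @export
stripe_model <- function(period = 8, amplitude = 0.2, axis = "y",
                         phase_offset = 0) {
  if (!(is_scalar_number(period) && period > 0)) stopf("period must be > 0")
  if (!(is_scalar_number(amplitude) && amplitude >= 0)) {
    stopf("amplitude must be >= 0")
  }
  if (!axis %in% c("y", "x")) stopf("axis must be 'y' or 'x'")
  structure(list(period = period, amplitude = amplitude, axis = axis,
                 phase_offset = phase_offset),
            class = "stripe_model")
}

stripe_field <- function(d, stripes) {
  ## modulation varies along the in-plane axis perpendicular to the
  ## stripe axis, constant along the stripes and across slices
  perp_axis <- if (stripes$axis == "y") 3L else 2L
  u <- seq_len(d[perp_axis]) - 1
  mod <- 1 + stripes$amplitude *
    sin(2 * pi * u / stripes$period + stripes$phase_offset)
  if (perp_axis == 3L) {
    aperm(array(mod, c(d[3L], d[1L], d[2L])), c(2L, 3L, 1L))
  } else {
    aperm(array(mod, c(d[2L], d[1L], d[3L])), c(2L, 1L, 3L))
  }
}

#' Simulate a single light-sheet view of a ground-truth volume
#'
#' Convolves the truth with the separable anisotropic Gaussian PSF, then
#' optionally applies multiplicative stripes, Poisson-like photon noise
#' (counts drawn at `photon_scale` photons per intensity unit, converted
#' back to intensity) and additive Gaussian read noise. All randomness is
#' governed by the explicit `seed`; the caller's RNG state is untouched.
#'
#' @param truth a [volume_stack()].
#' @param psf a [psf_model()].
#' @param stripes a [stripe_model()] or `NULL`.
#' @param noise `NULL` or a list with `photon_scale` (photons per
#'   intensity unit, > 0) and `read_sigma` (intensity units, >= 0).
#' @param seed integer seed.
#' @return A [volume_stack()].
#' @export
simulate_view <- function(truth, psf, stripes = NULL, noise = NULL, seed = 1L) {
  stopifnot(inherits(truth, "volume_stack"), inherits(psf, "psf_model"))
  ax <- match(psf$detection_axis, c("z", "y", "x"))
  sigma <- rep(psf$sigma_lateral, 3L)
  sigma[ax] <- psf$sigma_axial
  img <- gaussian_blur_3d(truth$data, sigma)
  if (!is.null(stripes)) {
    stopifnot(inherits(stripes, "stripe_model"))
    img <- img * stripe_field(dim(img), stripes)
  }
  if (!is.null(noise)) {
    ps <- noise$photon_scale %||% 0
    rs <- noise$read_sigma %||% 0
    img <- with_seed(seed, {
      if (ps > 0) img <- stats::rpois(length(img), lambda = img * ps) / ps
      if (rs > 0) img <- img + stats::rnorm(length(img), sd = rs)
      img
    })
    dim(img) <- dim(truth$data)
    img[img < 0] <- 0
  }
  volume_stack(img, voxel_size = truth$voxel_size, view_id = "view",
               dtype_range = truth$dtype_range)
}

#' Simulate an orthogonal pair of light-sheet views
#'
#' Renders the phantom once, then images it twice with the detection
#' axis along z: once as-is (view 1) and once after an exact 90-degree
#' rotation of the specimen about `tilt_axis` (view 2). In the common
#' frame the two axial-blur directions are therefore orthogonal — the
#' situation two orthogonal recordings of the same specimen produce.
#' The exact ground-truth rigid transform mapping view-1 coordinates
#' into view-2 coordinates is returned along with the views, so
#' registration can be bypassed or validated.
#'
#' @param spec a [phantom()]; in-plane dimensions of the tilt must be
#'   equal (e.g. a cubic grid).
#' @param psf a [psf_model()] (its `detection_axis` is overridden to
#'   `"z"` for both simulated cameras).
#' @param tilt_axis axis of the 90-degree specimen rotation.
#' @param stripes,noise forwarded to [simulate_view()]; view 2 receives
#'   an independent noise realization derived from `seed`.
#' @param seed integer seed.
#' @return A list with `view1`, `view2` ([volume_stack()]s), `transform`
#'   (the exact [rigid_transform()] for [resample()]ing view 2 onto view
#'   1's grid) and `truth`.
#' @export
simulate_view_pair <- function(spec, psf, tilt_axis = "y", stripes = NULL,
                               noise = NULL, seed = 1L) {
  stopifnot(inherits(spec, "phantom"))
  truth <- render_phantom(spec)
  psf1 <- psf_model(psf$sigma_lateral, psf$sigma_axial, "z")
  view1 <- simulate_view(truth, psf1, stripes, noise, seed = seed)
  rotated <- rot90_stack(truth, tilt_axis, 1L)
  view2 <- simulate_view(rotated, psf1, stripes, noise, seed = seed + 1000L)
  transform <- initial_transform_from_tilt(tilt_axis, 90,
                                           center = grid_center_um(truth))
  view1$view_id <- "I1"
  view2$view_id <- "I2"
  list(view1 = view1, view2 = view2, transform = transform, truth = truth)
}

#' Random cloud of Gaussian-blob sources
#'
#' Scatters point sources uniformly inside a sphere around the grid
#' center (so any rotation about the center keeps them in-domain), with
#' random intensities. Rendered and blurred with an isotropic PSF this
#' gives a rich, fully analytic texture for registration experiments:
#' the same cloud can be re-rendered at exactly transformed positions
#' with [transform_phantom()], producing a moving view whose true
#' alignment is known without any resampling step.
#'
#' @param dim grid shape `(z, y, x)` in voxels.
#' @param n_points number of sources.
#' @param radius_frac sphere radius as a fraction of the smallest grid
#'   extent.
#' @param intensity length-2 range of per-point intensity mass.
#' @param voxel_size µm per voxel.
#' @param seed integer seed; the cloud is a deterministic function of it.
#' @return A [phantom()].
#' @export
random_blob_phantom <- function(dim, n_points = 150, radius_frac = 0.33,
                                intensity = c(300, 1000), voxel_size = 1,
                                seed = 1L) {
  dim <- as.integer(rep_len(dim, 3L))
  vox <- rep_len(as.numeric(voxel_size), 3L)
  cen <- (dim - 1) / 2 * vox
  rad <- radius_frac * min((dim - 1) * vox)
  with_seed(seed, {
    dirs <- matrix(stats::rnorm(n_points * 3), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    r <- stats::runif(n_points)^(1 / 3) * rad
    pos <- sweep(dirs * r, 2, cen, `+`)
    ints <- stats::runif(n_points, intensity[1], intensity[2])
    prims <- lapply(seq_len(n_points), function(i) {
      list(kind = "point", position = pos[i, ], intensity = ints[i])
    })
    phantom(prims, dim, vox)
  })
}

#' Apply a rigid transform to a phantom's primitives
#'
#' Moves every primitive position through `transform` (point positions,
#' filament endpoints, shell centers), leaving intensities and the grid
#' unchanged. Rendering the result gives the scene as it appears in a
#' frame where `transform` maps the original coordinates — the exact,
#' interpolation-free way to construct a ground-truth moving view for
#' registration tests.
#'
#' @param spec a [phantom()].
#' @param transform a [rigid_transform()].
#' @return A [phantom()].
#' @export
transform_phantom <- function(spec, transform) {
  stopifnot(inherits(spec, "phantom"), inherits(transform, "rigid_transform"))
  mv <- function(p) as.numeric(apply_transform(transform, matrix(p, 3L)))
  prims <- lapply(spec$primitives, function(p) {
    if (p$kind == "point" || p$kind == "shell") {
      p$position <- mv(p$position)
    } else if (p$kind == "filament") {
      p$from <- mv(p$from)
      p$to <- mv(p$to)
    }
    p
  })
  phantom(prims, spec$dim, spec$voxel_size)
}
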