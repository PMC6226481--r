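#' Rigid transforms between volume coordinate frames
#'
#' A `rigid_transform` maps physical points (micrometres, component order
#' `(z, y, x)`) of the *fixed* frame into the *moving* frame:
#' `q = R (p - center) + center + translation`. This is the resampling
#' convention: to fill a voxel of the fixed grid, the transform says where
#' in the moving volume to interpolate.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1, acting on
#'   `(z, y, x)` components.
#' @param translation numeric length-3, micrometres.
#' @param center numeric length-3, rotation pivot in micrometres.
#'
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  center <- as.numeric(center)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L,
            length(center) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    stopf("rotation must be orthonormal")
  }
  if (det(rotation) < 0) stopf("rotation must be proper (det = +1)")
  structure(list(rotation = rotation, translation = translation,
                 center = center),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("rigid_transform: rotation %.3f deg, translation (%.3g, %.3g, %.3g) um\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

## total rotation angle (degrees) of an orthonormal matrix
rotation_angle_deg <- function(R) {
  c_ang <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, c_ang))) * 180 / pi
}

## principal-axis rotation matrix, components ordered (z, y, x),
## right-handed about the named physical axis
rotation_matrix_axis <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  cth <- cos(th); sth <- sin(th)
  switch(axis,
    z = matrix(c(1, 0, 0,
                 0, cth, sth,
                 0, -sth, cth), 3, 3, byrow = TRUE),
    y = matrix(c(cth, 0, -sth,
                 0, 1, 0,
                 sth, 0, cth), 3, 3, byrow = TRUE),
    x = matrix(c(cth, -sth, 0,
                 sth, cth, 0,
                 0, 0, 1), 3, 3, byrow = TRUE),
    stopf("axis must be one of 'z', 'y', 'x'")
  )
}

## intrinsic ZYX Euler composition for small optimizer increments
rotation_matrix_euler <- function(angles_deg) {
  rotation_matrix_axis("z", angles_deg[1L]) %*%
    rotation_matrix_axis("y", angles_deg[2L]) %*%
    rotation_matrix_axis("x", angles_deg[3L])
}

#' Physical center of a stack's voxel grid
#'
#' Voxel centers sit at `index * voxel_size` with 0-based indices, so the
#' grid center is `(dim - 1) / 2 * voxel_size` micrometres per axis.
#'
#' @param stack a [volume_stack()].
#' @return numeric length-3 `(z, y, x)` in micrometres.
#' @export
grid_center_um <- function(stack) {
  (dim(stack$data) - 1) / 2 * stack$voxel_size
}

#' Initial transform for a known acquisition tilt
#'
#' Builds the pure rotation that undoes an approximately known tilt
#' between two views (typically 90 degrees about the rotation axis of the
#' specimen mount), to seed [register_rigid()].
#'
#' @param axis `"z"`, `"y"` or `"x"` — the physical axis of the tilt.
#' @param angle tilt angle in degrees.
#' @param center rotation pivot in micrometres; use [grid_center_um()] of
#'   the fixed stack.
#'
#' @return A [rigid_transform()] with zero translation.
#' @examples
#' t90 <- initial_transform_from_tilt("y", 90)
#' @export
initial_transform_from_tilt <- function(axis, angle, center = c(0, 0, 0)) {
  if (!is_scalar_number(angle)) stopf("angle must be a finite scalar")
  rigid_transform(rotation_matrix_axis(axis, angle), c(0, 0, 0), center)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` is the transform applying `b` first, then
#' `a` — i.e. the map `p -> a(b(p))`. The composition of two rigid
#' transforms is again rigid.
#'
#' @param a,b [rigid_transform()] objects.
#' @return A [rigid_transform()] centered at `a$center`.
#' @export
compose_transforms <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  R <- a$rotation %*% b$rotation
  db <- b$center - b$rotation %*% b$center + b$translation   # b as q = Rb p + db
  d <- a$rotation %*% (db - a$center) + a$center + a$translation
  cen <- a$center
  trans <- as.numeric(d - cen + R %*% cen)
  rigid_transform(R, trans, cen)
}

#' Invert a rigid transform
#' @param t a [rigid_transform()].
#' @return The inverse [rigid_transform()], same center.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  rigid_transform(t(t$rotation), as.numeric(-t(t$rotation) %*% t$translation),
                  t$center)
}

#' Apply a rigid transform to physical points
#' @param t a [rigid_transform()].
#' @param pts 3 x n matrix of points, micrometres, rows `(z, y, x)`.
#' @return 3 x n matrix of mapped points.
#' @export
apply_transform <- function(t, pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) != 3L) stopf("pts must be a 3 x n matrix")
  t$rotation %*% (pts - t$center) + t$center + t$translation
}

#' Resample a volume under a rigid transform
#'
#' Interpolates `moving` onto a target grid: each target voxel center is
#' mapped through `transform` into the moving volume's physical frame and
#' sampled with trilinear interpolation. Voxels mapping outside the moving
#' domain are set to 0, consistent with downstream masking. This is how a
#' tilted stack is re-sampled into virtual slices coplanar with the
#' reference stack.
#'
#' @param moving a [volume_stack()].
#' @param transform a [rigid_transform()] mapping target physical
#'   coordinates to moving physical coordinates.
#' @param target a [volume_stack()] used as grid template, or a list with
#'   `dim` (length-3 integer) and `voxel_size` (length-3 µm). Defaults to
#'   the moving stack's own grid.
#'
#' @return A [volume_stack()] on the target grid.
#' @export
resample <- function(moving, transform, target = NULL) {
  stopifnot(inherits(moving, "volume_stack"),
            inherits(transform, "rigid_transform"))
  if (is.null(target)) target <- moving
  if (inherits(target, "volume_stack")) {
    tdim <- dim(target$data); tvox <- target$voxel_size
  } else {
    tdim <- as.integer(target$dim); tvox <- as.numeric(target$voxel_size)
  }
  if (any(tdim < 1L) || any(tvox <= 0)) stopf("target grid must be positive")
  ## index map: src_idx = diag(1/vox_m) %*% (R diag(vox_t) j + (c + t - R c))
  R <- transform$rotation
  off <- transform$center + transform$translation -
    as.numeric(R %*% transform$center)
  A <- diag(1 / moving$voxel_size) %*% R %*% diag(tvox)
  b <- off / moving$voxel_size
  out <- c_resample_trilinear(moving$data, dim(moving$data), A, b,
                              as.integer(tdim), 0)
  out[out < 0] <- 0
  volume_stack(out, voxel_size = tvox, view_id = moving$view_id,
               dtype_range = moving$dtype_range)
}

#' Exact 90-degree rotation by index permutation
#'
#' Rotates a stack by `k * 90` degrees about a principal axis through the
#' grid center using pure index permutation and reversal — no
#' interpolation. Agrees with [resample()] under the corresponding
#' [initial_transform_from_tilt()] and serves as the exact oracle for it.
#' The two in-plane dimensions must be equal so the grid maps onto itself.
#'
#' @param stack a [volume_stack()].
#' @param axis `"z"`, `"y"` or `"x"`.
#' @param k number of quarter turns (any integer; sign follows the same
#'   right-handed convention as [rotation_matrix_axis()]).
#' @return A [volume_stack()] on the same grid.
#' @export
rot90_stack <- function(stack, axis, k = 1L) {
  stopifnot(inherits(stack, "volume_stack"))
  k <- ((as.integer(k) %% 4L) + 4L) %% 4L
  a <- stack$data
  d <- dim(a)
  plane <- switch(axis, z = c(2L, 3L), y = c(1L, 3L), x = c(1L, 2L),
                  stopf("axis must be one of 'z', 'y', 'x'"))
  if (d[plane[1L]] != d[plane[2L]]) {
    stopf("in-plane dimensions must be equal for an exact 90-degree rotation")
  }
  rot1 <- function(a) {
    d <- dim(a)
    switch(axis,
      ## out[Z,y,X] = in[X, y, nx+1-Z]
      y = aperm(a, c(3L, 2L, 1L))[d[3L]:1L, , , drop = FALSE],
      ## out[z,Y,X] = in[z, ny+1-X, Y]
      z = aperm(a, c(1L, 3L, 2L))[, , d[2L]:1L, drop = FALSE],
      ## out[Z,Y,x] = in[Y, nz+1-Z, x]
      x = aperm(a, c(2L, 1L, 3L))[d[2L]:1L, , , drop = FALSE]
    )
  }
  for (i in seq_len(k)) a <- rot1(a)
  update_data(stack, a)
}

## block-mean downsampling by an integer factor (pyramid levels);
## trailing voxels that do not fill a block are dropped
downsample_stack <- function(stack, factor) {
  factor <- as.integer(factor)
  if (factor <= 1L) return(stack)
  d <- dim(stack$data)
  nd <- d %/% factor
  if (any(nd < 2L)) return(stack)
  a <- stack$data[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                  seq_len(nd[3] * factor), drop = FALSE]
  dim(a) <- c(factor, nd[1], factor * nd[2] * factor * nd[3])
  a <- colMeans(a)
  dim(a) <- c(nd[1], factor, nd[2] * factor * nd[3])
  a <- aperm(a, c(2L, 1L, 3L))
  a <- colMeans(a)
  dim(a) <- c(nd[1], nd[2], factor, nd[3])
  a <- aperm(a, c(3L, 1L, 2L, 4L))
  dim(a) <- c(factor, nd[1] * nd[2] * nd[3])
  a <- colMeans(a)
  dim(a) <- nd
  volume_stack(a, voxel_size = stack$voxel_size * factor,
               view_id = stack$view_id, dtype_range = stack$dtype_range)
}

ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a * a) * sum(b * b))
  if (den == 0) return(0)
  sum(a * b) / den
}

#' Rigid registration of a tilted view onto a reference view
#'
#' Estimates the rigid transform aligning `moving` to `fixed` by
#' maximizing normalized cross-correlation over a coarse-to-fine pyramid,
#' refined with Nelder-Mead. Both views image the same fluorophore, so the
#' mono-modal NCC metric suffices. The search is fully deterministic: a
#' fixed multiresolution schedule, no random restarts.
#'
#' The optimization parameterizes a small correction (ZYX Euler angles in
#' degrees, translation in micrometres, pivot at the fixed grid center)
#' composed onto `init`, so a good tilt initialization (e.g.
#' [initial_transform_from_tilt()] at the nominal 90 degrees) only needs a
#' few degrees of refinement.
#'
#' @param fixed,moving [volume_stack()] objects.
#' @param init a [rigid_transform()] initial guess (identity by default).
#' @param levels number of pyramid levels (downsampling factors
#'   `2^(levels-1), ..., 1`).
#' @param maxit Nelder-Mead iteration cap per level (recycled).
#' @return The optimized [rigid_transform()] (fixed frame to moving
#'   frame, ready for [resample()]).
#' @export
register_rigid <- function(fixed, moving, init = NULL, levels = 3L,
                           maxit = c(400L, 300L, 200L)) {
  stopifnot(inherits(fixed, "volume_stack"), inherits(moving, "volume_stack"))
  if (stats::sd(fixed$data) == 0 || stats::sd(moving$data) == 0) {
    stopf("no registrable content: constant image")
  }
  if (is.null(init)) {
    init <- rigid_transform(center = grid_center_um(fixed))
  }
  maxit <- rep_len(as.integer(maxit), levels)
  cen <- grid_center_um(fixed)
  par <- rep(0, 6)  # (rz, ry, rx deg, tz, ty, tx um) correction on init
  par_to_transform <- function(par) {
    delta <- rigid_transform(rotation_matrix_euler(par[1:3]), par[4:6], cen)
    compose_transforms(init, delta)
  }
  for (lev in seq(levels, 1L)) {
    f <- downsample_stack(fixed, 2L^(lev - 1L))
    m <- downsample_stack(moving, 2L^(lev - 1L))
    obj <- function(p) {
      r <- resample(m, par_to_transform(p), f)
      -ncc(f$data, r$data)
    }
    fit <- stats::optim(par, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit[levels - lev + 1L],
                                       reltol = 1e-10))
    par <- fit$par
    if (lev == 1L) {
      ## Nelder-Mead flattens out near the optimum; finish with cyclic
      ## 1D line searches at full resolution (deterministic)
      best <- obj(par)
      for (halfwidth in c(0.5, 0.1)) {
        for (j in 1:6) {
          o <- stats::optimize(function(v) {
            p <- par; p[j] <- v; obj(p)
          }, par[j] + c(-halfwidth, halfwidth), tol = 1e-4)
          if (o$objective < best) {
            par[j] <- o$minimum
            best <- o$objective
          }
        }
      }
    }
  }
  par_to_transform(par)
}

#' Write / read a rigid transform as plain text
#'
#' Serializes rotation (row-major), translation and center in micrometres
#' as a key-value text file for command-line interchange.
#'
#' @param t a [rigid_transform()].
#' @param path file path.
#' @return `write_transform`: `path` invisibly; `read_transform`: a
#'   [rigid_transform()].
#' @export
write_transform <- function(t, path) {
  stopifnot(inherits(t, "rigid_transform"))
  lines <- c(
    "# rigid transform: q = R (p - center) + center + translation",
    "# component order (z, y, x), units um",
    paste("rotation:", paste(format(t(t$rotation), digits = 17), collapse = " ")),
    paste("translation:", paste(format(t$translation, digits = 17), collapse = " ")),
    paste("center:", paste(format(t$center, digits = 17), collapse = " "))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, ":", fixed = TRUE)
  vals <- stats::setNames(
    lapply(kv, function(p) as.numeric(strsplit(trimws(p[2L]), "\\s+")[[1L]])),
    vapply(kv, function(p) trimws(p[1L]), "")
  )
  for (k in c("rotation", "translation", "center")) {
    if (is.null(vals[[k]])) stopf("transform file missing field '%s'", k)
  }
  rigid_transform(matrix(vals$rotation, 3, 3, byrow = TRUE),
                  vals$translation, vals$center)
}
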