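test_that("tilt transforms form a group", {
  t0 <- initial_transform_from_tilt("z", 0)
  expect_equal(t0$rotation, diag(3))
  expect_equal(t0$translation, c(0, 0, 0))

  t90 <- initial_transform_from_tilt("z", 90, center = c(5, 5, 5))
  t180 <- initial_transform_from_tilt("z", 180, center = c(5, 5, 5))
  twice <- compose_transforms(t90, t90)
  pts <- matrix(c(1, 2, 3, -4, 0, 9), nrow = 3)
  expect_equal(apply_transform(twice, pts), apply_transform(t180, pts))

  back <- compose_transforms(initial_transform_from_tilt("z", -90, c(5, 5, 5)),
                             t90)
  expect_equal(apply_transform(back, pts), pts)
  inv <- compose_transforms(invert_transform(t90), t90)
  expect_equal(apply_transform(inv, pts), pts)
})

test_that("rigid_transform enforces orthonormality", {
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  ## reflections are not rigid motions
  expect_error(rigid_transform(diag(c(-1, 1, 1))), "proper")
  t1 <- initial_transform_from_tilt("y", 37, c(1, 2, 3))
  expect_lt(max(abs(crossprod(t1$rotation) - diag(3))), 1e-10)
})

test_that("resample under exact 90-degree tilts matches index permutation", {
  v <- smooth_texture(20, seed = 21, sigma = 2)
  int <- 3:18  # interior, where interpolation has full support
  for (ax in c("z", "y", "x")) {
    rot <- rot90_stack(v, ax, 1L)
    t90 <- initial_transform_from_tilt(ax, 90, grid_center_um(v))
    back <- resample(rot, t90, v)
    expect_lt(max(abs(back$data[int, int, int] - v$data[int, int, int])),
              1e-12)
    ## four quarter-turns are the identity
    expect_equal(rot90_stack(v, ax, 4L)$data, v$data)
  }
})

test_that("resample is exact at lattice points", {
  v <- smooth_texture(12, seed = 3)
  ident <- rigid_transform(center = grid_center_um(v))
  expect_equal(resample(v, ident, v)$data, v$data)

  shift <- rigid_transform(translation = c(2, 0, -3))
  out <- resample(v, shift, v)
  ## out(p) = v(p + (2,0,-3)); vacated voxels are zero-filled
  expect_equal(out$data[1:10, , 4:12], v$data[3:12, , 1:9])
  expect_true(all(out$data[11:12, , ] == 0))
  expect_true(all(out$data[, , 1:3] == 0))
})

test_that("90-degree resampling of an axis-aligned bar conserves intensity", {
  a <- array(0, c(24, 24, 24))
  a[11:14, 11:14, 6:19] <- 100  # bar along x, interior
  v <- volume_stack(a)
  t90 <- initial_transform_from_tilt("y", 90, grid_center_um(v))
  rot <- resample(v, t90, v)
  ## bar now runs along z
  expect_gt(sum(rot$data[6:19, 11:14, 11:14]), 0.99 * sum(a))
  expect_lt(abs(sum(rot$data) / sum(a) - 1), 0.01)
  expect_equal(rot$data, rot90_stack(v, "y", -1L)$data, tolerance = 1e-12)
})

test_that("self-registration recovers the identity", {
  v <- add_read_noise(render_blob_view(random_blob_phantom(32, seed = 4)),
                      seed = 4)
  tr <- register_rigid(v, v, maxit = 150L)
  expect_lt(rotation_residual_deg(tr, rigid_transform()), 0.1)
  expect_lt(max(abs(tr$translation)), 0.1)
})

test_that("registration recovers a known translation", {
  ph <- random_blob_phantom(32, n_points = 80, seed = 9)
  true_t <- rigid_transform(translation = c(2, -1, 3))
  fixed <- add_read_noise(render_blob_view(ph), seed = 9)
  moving <- add_read_noise(render_blob_view(transform_phantom(ph, true_t)),
                           seed = 109)
  tr <- register_rigid(fixed, moving)
  expect_lt(max(abs(tr$translation - c(2, -1, 3))), 0.5)
  expect_lt(rotation_residual_deg(tr, true_t), 1)
})

test_that("constant images are rejected as unregistrable", {
  c1 <- volume_stack(array(1, c(8, 8, 8)))
  expect_error(register_rigid(c1, c1), "no registrable content")
})

test_that("transform files round-trip", {
  t1 <- compose_transforms(
    initial_transform_from_tilt("y", 92.5, c(10, 11, 12)),
    rigid_transform(translation = c(0.25, -3, 1e-4))
  )
  path <- withr::local_tempfile(fileext = ".txt")
  write_transform(t1, path)
  t2 <- read_transform(path)
  expect_equal(t2$rotation, t1$rotation, tolerance = 1e-14)
  expect_equal(t2$translation, t1$translation, tolerance = 1e-14)
  expect_equal(t2$center, t1$center, tolerance = 1e-14)
})
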