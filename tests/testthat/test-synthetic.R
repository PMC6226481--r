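test_that("phantom rendering conserves deposited mass", {
  empty <- render_phantom(phantom(list(), c(8, 8, 8)))
  expect_true(all(empty$data == 0))

  pt <- phantom(list(list(kind = "point", position = c(4, 4, 4),
                          intensity = 100)), c(9, 9, 9))
  v <- render_phantom(pt)
  expect_equal(sum(v$data), 100)
  expect_equal(v$data[5, 5, 5], 100)  # voxel-centered deposit

  sub <- phantom(list(list(kind = "point", position = c(4.5, 4, 4),
                           intensity = 100)), c(9, 9, 9))
  vs <- render_phantom(sub)
  expect_equal(sum(vs$data), 100)  # sub-voxel position splits, mass kept
  expect_equal(vs$data[5, 5, 5], 50)
  expect_equal(vs$data[6, 5, 5], 50)

  fil <- phantom(list(list(kind = "filament", from = c(2, 4, 4),
                           to = c(6, 4, 4), intensity = 30)), c(9, 9, 9))
  expect_equal(sum(render_phantom(fil)$data), 30, tolerance = 1e-12)

  expect_error(render_phantom(phantom(list(list(kind = "point",
                                                position = c(20, 4, 4),
                                                intensity = 1)),
                                      c(9, 9, 9))),
               "outside grid")
})

test_that("blob phantoms are deterministic in their seed", {
  p1 <- random_blob_phantom(24, seed = 5)
  p2 <- random_blob_phantom(24, seed = 5)
  p3 <- random_blob_phantom(24, seed = 6)
  expect_identical(render_phantom(p1)$data, render_phantom(p2)$data)
  expect_false(identical(render_phantom(p1)$data, render_phantom(p3)$data))
})

test_that("the simulated axial blur has the Gaussian closed-form FWHM", {
  ph <- phantom(list(list(kind = "point", position = c(24, 24, 24),
                          intensity = 1000)), c(49, 49, 49))
  view <- simulate_view(render_phantom(ph), psf_model(1.2, 4))
  w <- point_fwhm_3d(view, c(25, 25, 25))
  expect_equal(unname(w["z"]), 2 * sqrt(2 * log(2)) * 4, tolerance = 0.05)
  expect_equal(unname(w["y"]), 2 * sqrt(2 * log(2)) * 1.2, tolerance = 0.05)
  expect_equal(unname(w["x"]), 2 * sqrt(2 * log(2)) * 1.2, tolerance = 0.05)
})

test_that("blurring conserves interior intensity", {
  ph <- point_grid_phantom(c(32, 32, 32), spacing = 10, margin = 10)
  truth <- render_phantom(ph)
  view <- simulate_view(truth, psf_model(1.2, 3))
  expect_lt(abs(sum(view$data) / sum(truth$data) - 1), 0.005)
})

test_that("isotropic-PSF views are identical after an exact quarter turn", {
  ph <- random_blob_phantom(24, n_points = 40, seed = 12)
  truth <- render_phantom(ph)
  vz <- simulate_view(truth, psf_model(2, 2, detection_axis = "z"))
  vx <- simulate_view(truth, psf_model(2, 2, detection_axis = "x"))
  expect_equal(vz$data, vx$data, tolerance = 1e-12)
  ## and a rotated isotropic view maps back exactly
  rot <- rot90_stack(vz, "y", 1L)
  expect_equal(rot90_stack(rot, "y", -1L)$data, vz$data)
})

test_that("noise is reproducible per seed and differs across seeds", {
  truth <- render_phantom(point_grid_phantom(c(16, 16, 16), spacing = 8,
                                             margin = 4))
  noise <- list(photon_scale = 10, read_sigma = 0.5)
  a <- simulate_view(truth, psf_model(1, 2), noise = noise, seed = 3)
  b <- simulate_view(truth, psf_model(1, 2), noise = noise, seed = 3)
  c <- simulate_view(truth, psf_model(1, 2), noise = noise, seed = 4)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(simulate_view(render_phantom(point_grid_phantom(c(8, 8, 8),
                                                            margin = 3)),
                          psf_model(1, 1.5),
                          noise = list(photon_scale = 5, read_sigma = 0.1),
                          seed = 1))
  expect_identical(runif(1), before)
})

test_that("view pairs are consistent under the returned exact transform", {
  ph <- random_blob_phantom(32, n_points = 60, seed = 8)
  sim <- simulate_view_pair(ph, psf_model(2, 2), tilt_axis = "y", seed = 8)
  ## isotropic PSF: view2 resampled back equals view1 away from edges
  back <- resample(sim$view2, sim$transform, sim$view1)
  int <- 5:28
  expect_lt(max(abs(back$data[int, int, int] - sim$view1$data[int, int, int])),
            1e-10)
  ## exact 90-degree rotation, no translation component at the pivot
  expect_equal(sim$transform$translation, c(0, 0, 0))
  expect_equal(sim$transform$rotation %*% sim$transform$rotation %*%
                 sim$transform$rotation %*% sim$transform$rotation, diag(3))
})

test_that("orthogonal anisotropic views blur orthogonal axes", {
  ph <- phantom(list(list(kind = "point", position = c(20, 20, 20),
                          intensity = 1000)), c(41, 41, 41))
  sim <- simulate_view_pair(ph, psf_model(1.2, 4), tilt_axis = "y", seed = 2)
  w1 <- point_fwhm_3d(sim$view1, c(21, 21, 21))
  v2r <- resample(sim$view2, sim$transform, sim$view1)
  w2 <- point_fwhm_3d(v2r, c(21, 21, 21))
  expect_equal(names(which.max(w1)), "z")
  expect_equal(names(which.max(w2)), "x")  # axial blur rotated into x
})

test_that("multiplicative stripes modulate at the configured period", {
  truth <- volume_stack(array(1, c(4, 32, 32)))
  st <- stripe_model(period = 8, amplitude = 0.3, axis = "y",
                     phase_offset = pi / 2)
  v <- simulate_view(truth, psf_model(0.5, 0.5), stripes = st)
  prof <- v$data[2, 16, ]
  expect_equal(max(prof), 1.3, tolerance = 0.05)
  expect_equal(min(prof), 0.7, tolerance = 0.05)
  ## constant along the stripe axis
  expect_equal(v$data[2, 1, ], v$data[2, 32, ], tolerance = 1e-9)
})
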