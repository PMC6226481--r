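test_that("mutual masking zeroes each view outside the other's support", {
  a <- array(0, c(8, 8, 8))
  a[3:6, 3:6, 3:6] <- 10            # centered cube
  i2 <- volume_stack(a)
  set.seed(2)
  i1 <- volume_stack(array(runif(8^3, 1, 2), c(8, 8, 8)))
  out <- mutual_mask(i1, i2, threshold = 0.5)
  expect_true(all(out$i1$data[a == 0] == 0))
  expect_equal(out$i1$data[a > 0], i1$data[a > 0])
  expect_equal(out$i2$data, i2$data)  # i1 is everywhere above threshold
})

test_that("mutual masking of identical views keeps the supra-threshold set", {
  v <- smooth_texture(10, seed = 13)
  out <- mutual_mask(v, v, threshold = 0.5)
  keep <- v$data > 0.5
  expect_equal(out$i1$data[keep], v$data[keep])
  expect_true(all(out$i1$data[!keep] == 0))
  expect_equal(out$i1$data, out$i2$data)
})

test_that("disjoint supports raise a no-overlap error", {
  a <- array(0, c(6, 6, 6)); a[1:2, , ] <- 5
  b <- array(0, c(6, 6, 6)); b[5:6, , ] <- 5
  expect_error(mutual_mask(volume_stack(a), volume_stack(b), threshold = 1),
               "no overlap")
  expect_error(mutual_mask(volume_stack(array(0, c(4, 4, 4))),
                           volume_stack(array(0, c(4, 4, 4)))),
               "no overlap|normalized|all-zero")
})

test_that("percentile normalization maps the p-th percentile to 1", {
  set.seed(7)
  x <- array(runif(12^3, 1, 200), c(12, 12, 12))
  v <- volume_stack(x)
  n95 <- normalize_percentile(v, 95)
  expect_equal(stats::quantile(n95$data[n95$data > 0], 0.95, names = FALSE), 1)
  ## scale invariance
  n95k <- normalize_percentile(volume_stack(x * 17.3), 95)
  expect_equal(n95k$data, n95$data, tolerance = 1e-12)
  ## all-equal positive stack becomes all ones
  ones <- normalize_percentile(volume_stack(array(42, c(4, 4, 4))), 95)
  expect_true(all(ones$data == 1))
  expect_error(normalize_percentile(volume_stack(array(0, c(4, 4, 4)))),
               "all-zero")
})

test_that("spectral decomposition has the expected closed forms", {
  c4 <- spectral_decompose(volume_stack(array(3, c(4, 4, 4))))
  expect_equal(c4$magnitude[1, 1, 1], 3 * 64)
  expect_equal(max(c4$magnitude[-1]), 0)
  expect_equal(c4$phase[1, 1, 1], 0)

  imp <- array(0, c(4, 4, 4)); imp[1, 1, 1] <- 1
  si <- spectral_decompose(volume_stack(imp))
  expect_true(all(abs(si$magnitude - 1) < 1e-12))
  expect_true(all(abs(si$phase) < 1e-12))
})

test_that("real volumes give Hermitian-symmetric spectra", {
  set.seed(8)
  s <- spectral_decompose(volume_stack(array(runif(6 * 8 * 10), c(6, 8, 10))))
  neg <- function(i, n) (n - i + 2 - 1) %% n + 1  # frequency negation, 1-based
  d <- s$shape
  iz <- neg(seq_len(d[1]), d[1]); iy <- neg(seq_len(d[2]), d[2])
  ix <- neg(seq_len(d[3]), d[3])
  expect_lt(max(abs(s$magnitude - s$magnitude[iz, iy, ix])) /
              max(s$magnitude), 1e-8)
  F <- complex(modulus = s$magnitude, argument = s$phase)
  dim(F) <- d
  expect_lt(max(Mod(F - Conj(F[iz, iy, ix]))) / max(Mod(F)), 1e-8)
})

test_that("combining a spectrum with itself is the identity", {
  s <- spectral_decompose(smooth_texture(8, seed = 14))
  comb <- combine_spectra(s, s)
  expect_equal(comb$magnitude, s$magnitude)
  expect_equal(comb$phase, s$phase)
})

test_that("combination takes the max magnitude and the phase of the sum", {
  base <- array(0, c(2, 2, 2))
  mk <- function(mag, ph) {
    structure(list(magnitude = array(mag, c(2, 2, 2)),
                   phase = array(ph, c(2, 2, 2)),
                   shape = c(2, 2, 2), voxel_size = c(1, 1, 1)),
              class = "spectral_volume")
  }
  ## F1 = 3 (phase 0), F2 = 5i (phase pi/2): sum = 3 + 5i
  comb <- combine_spectra(mk(3, 0), mk(5, pi / 2))
  expect_equal(comb$magnitude[1, 1, 1], 5)
  expect_equal(comb$phase[1, 1, 1], atan2(5, 3), tolerance = 1e-12)

  ## exact cancellation: F1 = -F2 -> phase 0, magnitude max(M1, M2)
  canc <- combine_spectra(mk(4, pi / 3), mk(4, pi / 3 - pi))
  expect_equal(canc$magnitude[1, 1, 1], 4)
  expect_equal(canc$phase[1, 1, 1], 0)
})

test_that("recompose inverts spectral_decompose", {
  v <- smooth_texture(10, seed = 15)
  back <- recompose(spectral_decompose(v))
  expect_lt(nrmse(back$data, v$data), 1e-6)

  z <- spectral_decompose(volume_stack(array(0, c(4, 4, 4))))
  expect_true(all(recompose(z)$data == 0))
})

test_that("recompose rejects non-Hermitian spectra", {
  s <- spectral_decompose(smooth_texture(8, seed = 16))
  s$phase[2, 1, 1] <- s$phase[2, 1, 1] + 2  # break conjugate symmetry
  expect_error(recompose(s), "Hermitian")
})

test_that("polar pipeline matches the direct complex-arithmetic oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    a1 <- array(runif(16^3), c(16, 16, 16))
    a2 <- array(runif(16^3), c(16, 16, 16))
    fused <- recompose(combine_spectra(spectral_decompose(volume_stack(a1)),
                                       spectral_decompose(volume_stack(a2))),
                       clamp_negatives = FALSE)
    ## oracle: keep the larger-magnitude coefficient's modulus with the
    ## direction of F1 + F2, all in complex arithmetic
    F1 <- stats::fft(a1); F2 <- stats::fft(a2)
    S <- F1 + F2
    Fc <- pmax(Mod(F1), Mod(F2)) * S / ifelse(Mod(S) == 0, 1, Mod(S))
    oracle <- Re(stats::fft(Fc, inverse = TRUE)) / length(Fc)
    expect_lt(max(abs(fused - oracle)) / max(abs(oracle)), 1e-8)
  }
})

test_that("fusing a volume with itself reproduces it", {
  v <- smooth_texture(24, seed = 17)
  f <- fuse_views(v, v, fusion_config(mask_threshold = 0))
  expect_lt(scaled_nrmse(f$data, v$data), 1e-3)
})

test_that("fusion is symmetric in its two inputs", {
  ph <- point_grid_phantom(c(32, 32, 32), spacing = 12, margin = 8)
  sim <- simulate_view_pair(ph, psf_model(1.2, 3), seed = 31,
                            noise = list(photon_scale = 5, read_sigma = 0.02))
  i2r <- resample(sim$view2, sim$transform, sim$view1)
  f12 <- fuse_views(sim$view1, i2r, fusion_config())
  f21 <- fuse_views(i2r, sim$view1, fusion_config())
  expect_lt(max(abs(f12$data - f21$data)) / max(f12$data), 1e-6)
})

test_that("fused spectral magnitude dominates both inputs", {
  for (seed in 1:3) {
    v1 <- smooth_texture(16, seed = 40 + seed)
    v2 <- smooth_texture(16, seed = 80 + seed)
    s1 <- spectral_decompose(v1); s2 <- spectral_decompose(v2)
    comb <- combine_spectra(s1, s2)
    fused <- recompose(comb, clamp_negatives = FALSE)
    M <- Mod(stats::fft(fused))
    Mmax <- pmax(s1$magnitude, s2$magnitude)
    expect_lt(max(abs(M - Mmax)) / max(Mmax), 1e-6)
    ## spectral energy can only grow
    expect_gte(sum(comb$magnitude^2),
               max(sum(s1$magnitude^2), sum(s2$magnitude^2)))
  }
})

test_that("fusion of orthogonal anisotropic views restores isotropy", {
  ph <- point_grid_phantom(c(48, 48, 48), spacing = 16, margin = 16)
  sim <- simulate_view_pair(ph, psf_model(1.2, 4), tilt_axis = "y", seed = 5)
  i2r <- resample(sim$view2, sim$transform, sim$view1)
  pk <- arrayInd(which.max(sim$view1$data), dim(sim$view1$data))[1, ]
  w1 <- point_fwhm_3d(sim$view1, pk)
  fused <- fuse_views(sim$view1, i2r, fusion_config())
  pkf <- arrayInd(which.max(fused$data), dim(fused$data))[1, ]
  wf <- point_fwhm_3d(fused, pkf)
  expect_gt(max(w1) / min(w1), 2.5)
  expect_lt(max(wf) / min(wf), 1.3)
  expect_lt(max(wf), 1.3 * min(w1))
})
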