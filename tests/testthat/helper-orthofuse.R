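## shared fixture builders; everything is generated in code at test time

## smooth all-positive random texture (band-limited so registration and
## fusion behave like real images rather than white noise)
smooth_texture <- function(n, seed, sigma = 1.5, lo = 0.1, hi = 1) {
  set.seed(seed)
  a <- gaussian_blur_3d(array(runif(n^3, lo, hi), c(n, n, n)), sigma)
  volume_stack(a)
}

## additive Gaussian read noise at a target signal-to-noise ratio
add_read_noise <- function(v, seed, snr = 10) {
  set.seed(seed)
  d <- v$data + rnorm(length(v$data), sd = stats::sd(v$data) / snr)
  d[d < 0] <- 0
  volume_stack(d, v$voxel_size)
}

## render a blob-cloud phantom as an isotropically blurred view
render_blob_view <- function(ph, sigma = 1.5) {
  gaussian_blur_3d(render_phantom(ph), sigma)
}

nrmse <- function(a, b) sqrt(mean((a - b)^2)) / sqrt(mean(b^2))

## best-scale NRMSE: compares shapes irrespective of a global gain
scaled_nrmse <- function(a, b) {
  s <- sum(a * b) / sum(a * a)
  nrmse(a * s, b)
}

rotation_residual_deg <- function(t_est, t_true) {
  resid <- t_est$rotation %*% t(t_true$rotation)
  acos(min(1, max(-1, (sum(diag(resid)) - 1) / 2))) * 180 / pi
}
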