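hi_snr_phantom <- function() {
  if (is.null(fixture_env$hisnr)) {
    spec <- phantom_spec(grid_shape = c(24, 24, 8),
                         shells = list(c(1000, 12)), n_b0 = 4,
                         snr_b0 = 30, seed = 13)
    gt <- build_phantom(spec)
    fixture_env$hisnr <- list(gt = gt,
                              ds = add_complex_noise(gt$clean_signal, gt,
                                                     seed = 14))
  }
  fixture_env$hisnr
}

test_that("phase estimation preserves a constant phase and needs complex input", {
  # a uniform-magnitude slice with constant phase passes the low-pass filter
  # unchanged (the DC term carries everything)
  g <- gradient_table(c(0, 0), matrix(0, 2, 3))
  cplx <- dwi_dataset(array(1 + 0i, c(16, 16, 4, 2)) * exp(1i * 0.7), g,
                      domain = "complex")
  pf <- estimate_phase_field(cplx)
  expect_lt(max(abs(Arg(exp(1i * (pf$phase - 0.7))))), 1e-8)

  expect_error(estimate_phase_field(as_magnitude(cplx)), "complex")
})

test_that("the low-pass estimator recovers smooth phase at high SNR", {
  p <- hi_snr_phantom()
  gt <- p$gt
  pf <- estimate_phase_field(p$ds)
  obj <- gt$rois$object
  b0 <- b0_indices(gt$grad)
  # wrap-aware error against the generated smooth field, b = 0 volumes
  err <- Arg(exp(1i * (pf$phase[, , , b0] - gt$phase_field[, , , b0])))
  rms <- sqrt(mean(err[rep(obj, length(b0))]^2))
  expect_lt(rms, 0.05)
})

test_that("high-spatial-frequency phase jitter is strongly attenuated", {
  spec <- phantom_spec(grid_shape = c(24, 24, 8), shells = list(c(1000, 6)),
                       n_b0 = 2, snr_b0 = 30,
                       phase_model = "smooth_plus_jitter", seed = 21)
  gt <- build_phantom(spec)
  # noiseless data, estimated with and without the jitter component: the
  # difference isolates the filter's response to the jitter itself
  with_jit <- dwi_dataset(gt$clean_signal * exp(1i * gt$phase_field),
                          gt$grad, gt$voxel_size, "complex")
  smooth_only <- dwi_dataset(gt$clean_signal * exp(1i * gt$phase_smooth),
                             gt$grad, gt$voxel_size, "complex")
  pf_j <- estimate_phase_field(with_jit)
  pf_s <- estimate_phase_field(smooth_only)
  # band-power comparison inside the object (the phase of zero-signal
  # background is meaningless): in the jitter's own frequency band the
  # estimate carries far less power than the jitter that was injected
  # (10x in RMS = 100x in power)
  fr <- function(n) { k <- 0:(n - 1); ifelse(k > n / 2, k - n, k) / (n / 2) }
  band <- sqrt(outer(fr(24)^2, fr(24)^2, `+`)) > 0.9
  obj <- gt$rois$object
  band_power <- function(field4) {
    tot <- 0
    for (v in 1:2) for (z in 1:8)
      tot <- tot + sum(Mod(fft(field4[, , z, v] * obj[, , z]))[band]^2)
    tot
  }
  leak_p <- band_power(Arg(exp(1i * (pf_j$phase - pf_s$phase))))
  jit_p <- band_power(gt$phase_field - gt$phase_smooth)
  expect_lt(leak_p, jit_p / 100)
})

test_that("rotation to the real axis cancels the phase and the noise floor", {
  p <- small_phantom()
  gt <- p$gt

  # zero phase field: rotation is the identity on the real channel
  pf0 <- true_phase_field(gt)
  pf0$phase[] <- 0
  r0 <- rotate_to_real(p$ds, pf0)
  expect_equal(r0$data, Re(p$ds$data), ignore_attr = TRUE)

  # noiseless data with the true phase come back exactly
  cplx <- dwi_dataset(gt$clean_signal * exp(1i * gt$phase_field), gt$grad,
                      gt$voxel_size, "complex")
  rc <- rotate_to_real(cplx, true_phase_field(gt))
  expect_lt(max(abs(rc$data - gt$clean_signal)), 1e-10)
  # and taking the magnitude afterwards returns the original magnitude
  expect_equal(Mod(rc$data), Mod(cplx$data), tolerance = 1e-12,
               ignore_attr = TRUE)

  # zero-signal ROI: rotated mean ~ 0, magnitude mean ~ 1.2533 sigma
  bg <- gt$rois$background
  dwv <- dw_indices(gt$grad)
  rot_bg <- p$rot$data[, , , dwv][rep(bg, length(dwv))]
  mag_bg <- p$mag$data[, , , dwv][rep(bg, length(dwv))]
  expect_lt(abs(mean(rot_bg)) / p$sigma, 0.05)
  expect_equal(mean(mag_bg) / p$sigma, sqrt(pi / 2), tolerance = 0.02)

  bad <- true_phase_field(build_phantom(
    phantom_spec(grid_shape = c(14, 14, 8), shells = list(c(1000, 4)),
                 n_b0 = 1, seed = 1)))
  expect_error(rotate_to_real(p$ds, bad), "geometry")
})

test_that("complex and magnitude averaging behave as CLT vs Rayleigh predict", {
  spec <- phantom_spec(grid_shape = c(16, 16, 10),
                       shells = list(c(1000, 10), c(2000, 10)), n_b0 = 3,
                       snr_b0 = 10, seed = 23)
  gt <- build_phantom(spec)
  sig <- 1 / 10
  reps <- make_repeats(gt, n_repeats = 6, seed = 40)
  pf <- true_phase_field(gt)
  rot <- lapply(reps, rotate_to_real, pf = pf)
  mags <- lapply(reps, as_magnitude)

  # single repeat: both averages are the identity
  expect_identical(complex_average(rot[1])$data, rot[[1]]$data)
  expect_identical(magnitude_average(mags[1])$data, mags[[1]]$data)

  bg <- gt$rois$background
  dwv <- dw_indices(gt$grad)
  pool <- function(x) x[, , , dwv][rep(bg, length(dwv))]

  rmse_prev <- Inf
  for (R in c(2, 4, 6)) {
    ca <- complex_average(rot[1:R])
    ma <- magnitude_average(mags[1:R])
    # complex average: noise std shrinks by sqrt(R), mean stays ~0
    expect_equal(sig / sd(pool(ca$data)), sqrt(R), tolerance = 0.05)
    expect_lt(abs(mean(pool(ca$data))) / sig, 0.05)
    # magnitude average: the Rayleigh mean survives averaging
    expect_equal(mean(pool(ma$data)) / sig, sqrt(pi / 2), tolerance = 0.03)
    # complex-average RMSE against the clean signal keeps falling
    rmse <- sqrt(mean((ca$data - gt$clean_signal)^2))
    expect_lt(rmse, rmse_prev)
    rmse_prev <- rmse
  }

  # in the maximally attenuated ROI the complex average is closer to truth
  csf <- gt$rois$csf_like
  b2 <- shell_indices(reps[[1]], 2000)
  ca <- complex_average(rot); ma <- magnitude_average(mags)
  bias <- function(x) abs(mean((x[, , , b2] - gt$clean_signal[, , , b2])[
    rep(csf, length(b2))]))
  expect_lt(bias(ca$data), bias(ma$data))

  # at high SNR (b = 0 volumes in the object) the two averages agree to ~1%
  b0 <- b0_indices(gt$grad)
  obj <- gt$rois$object & !gt$rois$csf_like
  hi_ca <- mean(ca$data[, , , b0][rep(obj, length(b0))])
  hi_ma <- mean(ma$data[, , , b0][rep(obj, length(b0))])
  expect_equal(hi_ma / hi_ca, 1, tolerance = 0.01)

  expect_error(complex_average(mags), "real_rotated")
  expect_error(magnitude_average(rot), "magnitude")
})
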