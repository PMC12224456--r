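# Shared fixtures, built once per test run and cached.  Everything is
# generated in code; nothing is read from disk.

fixture_env <- new.env(parent = emptyenv())

# Small two-shell phantom at moderate SNR for module-level tests.
small_phantom <- function() {
  if (is.null(fixture_env$small)) {
    spec <- phantom_spec(grid_shape = c(20, 20, 12),
                         shells = list(c(1000, 20), c(2000, 20)),
                         n_b0 = 8, snr_b0 = 15, seed = 5)
    gt <- build_phantom(spec)
    ds <- add_complex_noise(gt$clean_signal, gt, seed = 50)
    fixture_env$small <- list(gt = gt, ds = ds, sigma = 1 / 15,
                              mag = as_magnitude(ds),
                              rot = rotate_to_real(ds, true_phase_field(gt)))
  }
  fixture_env$small
}

# The SNR-5 evaluation phantom with all four denoisers applied, used by the
# acceptance suite: b = 1000 (48 directions, supports an L = 8 SH fit) and
# b = 2000 (24 directions, maximal attenuation) shells plus 6 b = 0 volumes.
acceptance_fixture <- function() {
  if (is.null(fixture_env$acc)) {
    spec <- phantom_spec(grid_shape = c(36, 36, 18),
                         shells = list(c(1000, 48), c(2000, 24)),
                         n_b0 = 6, snr_b0 = 5, seed = 7)
    gt <- build_phantom(spec)
    ds <- add_complex_noise(gt$clean_signal, gt, seed = 11)
    mag <- as_magnitude(ds)
    rot <- rotate_to_real(ds, true_phase_field(gt))
    noise_map <- estimate_noise_map(rot)
    den <- list(
      mppca_mag  = mppca_denoise(mag)$denoised,
      mppca_cplx = mppca_denoise(rot)$denoised,
      nordic     = nordic_denoise(rot, patch_spec(11, stride = 2),
                                  noise_map = noise_map, seed = 3)$denoised,
      nlm        = nlm_denoise_dataset(mag, search_radius = 2))
    clean <- dwi_dataset(gt$clean_signal, gt$grad, gt$voxel_size, "magnitude")
    wm <- gt$rois$single_fibre | gt$rois$crossing | gt$rois$tissue
    truth <- fit_dti(clean, mask = wm)
    fixture_env$acc <- list(gt = gt, ds = ds, mag = mag, rot = rot,
                            noise_map = noise_map, den = den, clean = clean,
                            wm = wm, truth = truth, sigma = 0.2)
  }
  fixture_env$acc
}

# Noiseless single-voxel-style dataset generated directly from the tensor
# model: the exactness oracle for the DTI/DKI fits.
tensor_dataset <- function(D, s0 = 100, bvals = NULL, bvecs = NULL,
                           dims = c(4, 4, 4), seed = 2) {
  if (is.null(bvals)) {
    dirs <- uniform_directions(30, seed = seed)
    bvals <- c(rep(0, 5), rep(1000, 30))
    bvecs <- rbind(matrix(0, 5, 3), dirs)
  }
  grad <- gradient_table(bvals, bvecs)
  sig <- vapply(seq_along(bvals), function(j) {
    g <- bvecs[j, ]
    s0 * exp(-bvals[j] * as.numeric(t(g) %*% D %*% g))
  }, numeric(1))
  arr <- array(rep(sig, each = prod(dims)), c(dims, length(bvals)))
  dwi_dataset(arr, grad, domain = "magnitude")
}
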