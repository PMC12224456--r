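test_that("default patch sizes follow the P^3 >= N and 11:1 rules", {
  expect_identical(default_patch_size(105, "mppca"), 5L)
  expect_identical(default_patch_size(300, "mppca"), 7L)
  expect_identical(default_patch_size(105, "nordic"), 11L)
  expect_identical(default_patch_size(1, "mppca"), 3L)
  # the rule is monotone in N
  ps <- vapply(c(10, 50, 200, 800), default_patch_size, integer(1),
               method = "mppca")
  expect_true(all(diff(ps) >= 0))
})

test_that("patch_spec validates its fields", {
  expect_error(patch_spec(4), "odd")
  expect_error(patch_spec(1), "odd")
  expect_error(patch_spec(5, stride = 7), "stride")
  expect_identical(patch_spec(5)$aggregation, "average")
})

test_that("mp_threshold handles degenerate and planted spectra", {
  r0 <- mp_threshold(rep(0, 10), M = 125)
  expect_identical(r0$rank, 0L)
  expect_identical(r0$sigma2, 0)

  expect_error(mp_threshold(c(1, 2, 3), M = 125), "non-increasing")

  # planted rank-1 component far above the MP edge is found
  set.seed(77)
  M <- 125; N <- 60; g <- N / M
  u <- rnorm(M); v <- rnorm(N)
  X <- matrix(rnorm(M * N), M, N) +
    outer(u / sqrt(sum(u^2)), v / sqrt(sum(v^2))) * sqrt(50 * (1 + sqrt(g))^2 * M)
  lam <- sort(eigen(crossprod(X) / M, symmetric = TRUE,
                    only.values = TRUE)$values, decreasing = TRUE)
  r1 <- mp_threshold(lam, M, N)
  expect_identical(r1$rank, 1L)
  expect_equal(r1$sigma2, 1, tolerance = 0.1)
  expect_equal(r1$gamma, g)
})

test_that("MP-PCA leaves noiseless data untouched and reduces noisy RMSE", {
  p <- small_phantom()
  gt <- p$gt

  clean <- dwi_dataset(gt$clean_signal, gt$grad, gt$voxel_size, "magnitude")
  out <- mppca_denoise(clean, patch_spec(5))
  rel <- max(abs(out$denoised$data - gt$clean_signal)) /
    max(gt$clean_signal)
  expect_lt(rel, 1e-8)

  rmse <- function(x) sqrt(mean((x - gt$clean_signal)[gt$clean_signal > 0]^2))
  for (ds in list(p$mag, p$rot)) {
    den <- mppca_denoise(ds)
    expect_lt(rmse(den$denoised$data), rmse(ds$data))
    # sigma map recovers the true noise level
    expect_equal(mean(den$sigma_map), p$sigma, tolerance = 0.1)
  }

  # zero-signal ROI: the real-rotated output is floor-free, the magnitude
  # output keeps the Rayleigh floor
  bg <- gt$rois$background
  dwv <- dw_indices(gt$grad)
  den_rot <- mppca_denoise(p$rot)$denoised
  den_mag <- mppca_denoise(p$mag)$denoised
  m_rot <- mean(den_rot$data[, , , dwv][rep(bg, length(dwv))]) / p$sigma
  m_mag <- mean(den_mag$data[, , , dwv][rep(bg, length(dwv))]) / p$sigma
  expect_lt(abs(m_rot), 0.3)
  expect_gt(m_mag, 0.8)

  expect_error(mppca_denoise(p$ds), "rotate")
  expect_error(mppca_denoise(p$mag, patch_spec(21)), "exceeds")
})

test_that("patch aggregation is conservative", {
  # a constant dataset stays exactly constant under any aggregation
  g <- gradient_table(c(0, rep(1000, 9)),
                      rbind(c(0, 0, 0), uniform_directions(9, seed = 1)))
  arr <- array(5, c(9, 9, 9, 10))
  ds <- dwi_dataset(arr, g)
  for (agg in c("average", "center_only")) {
    out <- mppca_denoise(ds, patch_spec(3, stride = 1, aggregation = agg))
    expect_equal(out$denoised$data, arr, tolerance = 1e-10)
  }
})

test_that("the NORDIC threshold removes pure noise and keeps planted signal", {
  M <- 125; N <- 40
  tau <- nordic_threshold(M, N, n_mc = 40, seed = 5)
  expect_identical(tau, nordic_threshold(M, N, n_mc = 40, seed = 5))
  expect_gt(tau, sqrt(M) + sqrt(N) - 4)        # near the Gaussian edge
  expect_lt(tau, sqrt(M) + sqrt(N) + 4)

  g <- gradient_table(c(0, rep(1000, N - 1)),
                      rbind(c(0, 0, 0), uniform_directions(N - 1, seed = 2)))
  set.seed(6)
  noise <- array(rnorm(11^3 * N), c(11, 11, 11, N))
  ds <- dwi_dataset(noise, g, domain = "real_rotated")
  ones <- array(1, c(11, 11, 11))
  out <- nordic_denoise(ds, patch_spec(5, stride = 2), noise_map = ones,
                        n_mc = 40, seed = 5)
  expect_lt(var(as.vector(out$denoised$data)), 0.1)
  expect_lt(mean(out$rank_map, na.rm = TRUE), 0.05 * N)

  # planted rank-1 with singular value 3 tau is retained within 5%
  tau11 <- nordic_threshold(11^3, N, n_mc = 40, seed = 5)
  u <- rnorm(11^3); v <- rnorm(N)
  planted <- 3 * tau11 * outer(u / sqrt(sum(u^2)), v / sqrt(sum(v^2)))
  X_in <- as.vector(planted) + rnorm(11^3 * N)
  ds2 <- dwi_dataset(array(X_in, c(11, 11, 11, N)), g,
                     domain = "real_rotated")
  out2 <- nordic_denoise(ds2, patch_spec(11, stride = 11), noise_map = ones,
                         n_mc = 40, seed = 5)
  sv_in <- svd(matrix(X_in, 11^3, N), nu = 0, nv = 0)$d[1]
  sv_out <- svd(matrix(out2$denoised$data, 11^3, N), nu = 0, nv = 0)$d[1]
  expect_equal(sv_out, sv_in, tolerance = 1e-8)  # kept exactly, not shrunk
  expect_equal(sv_out, 3 * tau11, tolerance = 0.05)

  expect_error(nordic_denoise(ds, noise_map = ones * 0), "positive")
  expect_error(nordic_denoise(as_magnitude(small_phantom()$ds),
                              noise_map = ones), "real-rotated")
})

test_that("variance normalisation flattens spatially varying noise", {
  spec <- phantom_spec(grid_shape = c(20, 20, 12), shells = list(c(1000, 12)),
                       n_b0 = 3, snr_b0 = 10,
                       sigma_map_model = "radial_gradient", seed = 31)
  gt <- build_phantom(spec)
  ds <- add_complex_noise(gt$clean_signal, gt, seed = 32)
  rot <- rotate_to_real(ds, true_phase_field(gt))
  # dividing by the true sigma map leaves unit noise everywhere: the std of
  # the normalised background is flat within 10%
  bg <- gt$rois$background
  dwv <- dw_indices(gt$grad)
  norm <- sweep(rot$data, 1:3, gt$sigma_map, `/`)
  half <- dim(norm)[3] %/% 2
  s_top <- sd(norm[, , 1:half, dwv][rep(bg[, , 1:half], length(dwv))])
  s_bot <- sd(norm[, , -(1:half), dwv][rep(bg[, , -(1:half)], length(dwv))])
  expect_equal(s_top / s_bot, 1, tolerance = 0.1)

  # NORDIC with the estimated map still reduces RMSE under varying sigma
  nm <- estimate_noise_map(rot)
  out <- nordic_denoise(rot, noise_map = nm, n_mc = 40, seed = 7)
  rmse <- function(x) sqrt(mean((x - gt$clean_signal)^2))
  expect_lt(rmse(out$denoised$data), rmse(rot$data))
})

test_that("noise maps are recovered from b=0 repeats", {
  p <- small_phantom()
  nm <- estimate_noise_map(p$rot)
  expect_equal(mean(nm) / p$sigma, 1, tolerance = 0.1)

  spec <- phantom_spec(grid_shape = c(20, 20, 12), shells = list(c(1000, 8)),
                       n_b0 = 6, snr_b0 = 10,
                       sigma_map_model = "radial_gradient", seed = 33)
  gt <- build_phantom(spec)
  ds <- add_complex_noise(gt$clean_signal, gt, seed = 34)
  nm2 <- estimate_noise_map(rotate_to_real(ds, true_phase_field(gt)))
  expect_gt(cor(as.vector(nm2), as.vector(gt$sigma_map)), 0.9)

  one_b0 <- subset_volumes(p$rot, c(b0_indices(p$rot$grad)[1],
                                    dw_indices(p$rot$grad)))
  expect_error(estimate_noise_map(one_b0), "at least 2")
})

test_that("non-local means respects its limits and reduces noise", {
  # constant image: all patches identical, output equals input
  cvol <- array(3, c(12, 12, 12))
  expect_equal(nlm_denoise(cvol, sigma = 1), cvol, tolerance = 1e-12)

  # sigma -> 0: weights collapse onto self
  set.seed(12)
  vol <- array(rnorm(12^3, 10), c(12, 12, 12))
  out <- nlm_denoise(vol, sigma = 1e-6)
  expect_equal(out, vol, tolerance = 1e-4)

  # noisy phantom volume: RMSE falls
  p <- small_phantom()
  v <- dw_indices(p$gt$grad)[1]
  noisy <- p$mag$data[, , , v]
  den <- nlm_denoise(noisy, sigma = p$sigma, search_radius = 3)
  clean <- p$gt$clean_signal[, , , v]
  expect_lt(sqrt(mean((den - clean)^2)), sqrt(mean((noisy - clean)^2)))

  expect_error(nlm_denoise(vol, sigma = 0), "sigma > 0")
})
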