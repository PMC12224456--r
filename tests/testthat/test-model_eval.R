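test_that("the log-linear DTI fit is exact on noiseless tensor data", {
  # isotropic CSF-like tensor
  ds_iso <- tensor_dataset(diag(rep(3e-3, 3)))
  f <- fit_dti(ds_iso, 1000)
  expect_equal(max(abs(f$md - 3e-3)), 0, tolerance = 1e-12)
  expect_lt(max(f$fa), 1e-9)
  expect_equal(max(abs(f$s0 - 100)), 0, tolerance = 1e-9)
  expect_lt(max(abs(f$residuals)), 1e-9)

  # prolate tensor: FA and principal axis recovered
  R <- function(th) rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0),
                          c(0, 0, 1))
  D <- R(0.6) %*% diag(c(1.7, 0.2, 0.2) * 1e-3) %*% t(R(0.6))
  f2 <- fit_dti(tensor_dataset(D), 1000)
  expect_equal(f2$fa[1, 1, 1], 0.8703883, tolerance = 1e-6)
  v1 <- f2$v1[1, 1, 1, ]
  axis <- R(0.6)[, 1]
  ang <- acos(min(abs(sum(v1 * axis)), 1)) * 180 / pi
  expect_lt(ang, 0.5)

  # FA is invariant to a global rescaling of the signal
  ds_scaled <- ds_iso
  ds_scaled$data <- ds_scaled$data * 17
  f3 <- fit_dti(ds_scaled, 1000)
  expect_equal(f3$fa, f$fa, tolerance = 1e-9)

  expect_error(fit_dti(subset_volumes(ds_iso, 1:6), 1000), ">= 7")
})

test_that("WLS agrees with OLS on noiseless data", {
  D <- diag(c(1.2, 0.5, 0.4) * 1e-3)
  ds <- tensor_dataset(D, dims = c(3, 3, 3))
  fo <- fit_dti(ds, 1000, method = "ols")
  fw <- fit_dti(ds, 1000, method = "wls")
  expect_equal(fw$md, fo$md, tolerance = 1e-10)
  expect_equal(fw$fa, fo$fa, tolerance = 1e-8)
})

test_that("the kurtosis fit nests the tensor model", {
  dirs1 <- uniform_directions(24, seed = 8)
  dirs2 <- uniform_directions(24, seed = 9)
  bv <- c(rep(0, 4), rep(1000, 24), rep(2000, 24))
  bvec <- rbind(matrix(0, 4, 3), dirs1, dirs2)
  D <- diag(c(1.5, 0.4, 0.3) * 1e-3)
  ds <- tensor_dataset(D, bvals = bv, bvecs = bvec, dims = c(3, 3, 3))
  fk <- fit_dki(ds)
  # tensor-generated data: kurtosis terms vanish, residuals ~ 0
  expect_lt(max(abs(fk$coeffs[8:22, ])), 1e-10)
  expect_lt(max(abs(fk$residuals)), 1e-8)
  expect_equal(unname(fk$coeffs[2, 1]), 1.5e-3, tolerance = 1e-10)

  # residual smoothness from DKI tracks the DTI residual smoothness
  p <- small_phantom()
  obj <- p$gt$rois$object
  fd <- fit_dti(p$mag, mask = obj)
  rd <- standardized_residuals(p$mag$data[, , , fd$volumes],
                               predict_dti(fd), obj)
  fk2 <- fit_dki(p$mag, mask = obj)
  rk <- standardized_residuals(p$mag$data[, , , fk2$volumes],
                               fk2$prediction, obj)
  # raw-data residuals are nearly white, so the formula's clip warning is
  # expected here
  ed <- suppressWarnings(estimate_fwhm(rd, obj, p$mag$voxel_size))
  ek <- suppressWarnings(estimate_fwhm(rk, obj, p$mag$voxel_size))
  expect_equal(ek$fwhm_mm / ed$fwhm_mm, rep(1, 3), tolerance = 0.15,
               ignore_attr = TRUE)
})

test_that("wild bootstrap is exact in the noiseless limit and seeded", {
  D <- diag(c(1.2, 0.5, 0.4) * 1e-3)
  ds <- tensor_dataset(D, dims = c(3, 3, 3))
  wb <- wild_bootstrap(ds, 1000, n = 25, seed = 1)
  # zero residuals: replicates identical up to float roundoff
  expect_lt(max(wb$fa_sd, na.rm = TRUE), 1e-6)
  expect_lt(max(wb$md_sd, na.rm = TRUE), 1e-9)

  # identical seeds reproduce; different seeds agree in distribution
  p <- small_phantom()
  fib <- p$gt$rois$single_fibre
  w1 <- wild_bootstrap(p$mag, mask = fib, n = 250, seed = 4)
  w1b <- wild_bootstrap(p$mag, mask = fib, n = 250, seed = 4)
  w2 <- wild_bootstrap(p$mag, mask = fib, n = 250, seed = 5)
  expect_identical(w1$fa_sd, w1b$fa_sd)
  expect_equal(median(w2$fa_sd, na.rm = TRUE) /
               median(w1$fa_sd, na.rm = TRUE), 1, tolerance = 0.05)
})

test_that("accuracy scores behave under added noise", {
  p <- small_phantom()
  mask <- p$gt$rois$object
  set.seed(60)                       # a spatially varying reference map
  ref <- gaussian_smooth_volume(array(rnorm(prod(dim(p$gt$s0_map))),
                                      dim(p$gt$s0_map)), 2)
  self <- accuracy_vs_reference(ref, ref, mask)
  expect_equal(self$pearson_r, 1)
  expect_equal(self$sse, 0)

  set.seed(61)
  rs <- vapply(c(0.05, 0.2, 0.8), function(s) {
    noisy <- ref + array(rnorm(length(ref), 0, s), dim(ref))
    accuracy_vs_reference(noisy, ref, mask)$pearson_r
  }, numeric(1))
  expect_true(all(diff(rs) < 0))               # r falls as noise grows
})

test_that("direction subsets are uniform, seeded and convergent", {
  dirs <- uniform_directions(48, seed = 71)
  s1 <- subset_directions(dirs, 16, seed = 3)
  expect_identical(s1, subset_directions(dirs, 16, seed = 3))
  expect_length(unique(s1), 16L)
  expect_identical(subset_directions(dirs, 48, seed = 3), 1:48)

  # maximin subsets spread out at least as well as a random pick
  ang <- function(idx) {
    ca <- abs(dirs[idx, ] %*% t(dirs[idx, ])); diag(ca) <- 0
    acos(max(pmin(ca, 1)))
  }
  set.seed(4)
  expect_gte(ang(s1), ang(sample(48, 16)))

  # fraction 1.0 against the data's own fit gives r = 1
  p <- small_phantom()
  wm <- p$gt$rois$single_fibre | p$gt$rois$crossing | p$gt$rois$tissue
  own <- fit_dti(p$mag, mask = wm)
  tab <- subset_convergence(p$mag, 1, list(fa = own$fa, md = own$md), wm,
                            seed = 5)
  expect_equal(tab$fa_r, 1, tolerance = 1e-12)
  expect_equal(tab$md_r, 1, tolerance = 1e-12)

  # r increases with the kept fraction on noisy data
  clean <- dwi_dataset(p$gt$clean_signal, p$gt$grad, p$gt$voxel_size,
                       "magnitude")
  truth <- fit_dti(clean, mask = wm)
  tab2 <- subset_convergence(p$mag, c(0.35, 0.65, 1),
                             list(fa = truth$fa, md = truth$md), wm, seed = 5)
  expect_true(all(diff(tab2$fa_r) > 0))
})
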