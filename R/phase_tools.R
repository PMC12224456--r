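#' Estimate a smooth phase field from complex data
#'
#' Per slice and volume: 2-D FFT of the complex slice, multiplication by a
#' radially symmetric Tukey (tapered-cosine) low-pass window, inverse FFT,
#' and the argument of the result.  The window's half-maximum radius sits at
#' `filter_fwhm_fraction` of the Nyquist radius (the `"radius"` convention;
#' `"diameter"` halves it), with a cosine taper of total width `taper` in the
#' same normalised units.  Smooth phase variation (shot-to-shot B0 drift,
#' residual coil phase) passes; high-spatial-frequency content is rejected.
#'
#' @param ds a complex-domain `dwi_dataset`.
#' @param filter_fwhm_fraction half-maximum radius as a fraction of the
#'   Nyquist radius; default 0.58.
#' @param taper cosine taper width (fraction of the Nyquist radius).
#' @param convention `"radius"` (default) or `"diameter"`.
#' @return object of class `phase_field`: the 4-D phase array (radians,
#'   wrapped to (-pi, pi]) plus the filter settings.
#' @export
estimate_phase_field <- function(ds, filter_fwhm_fraction = 0.58,
                                 taper = 0.2,
                                 convention = c("radius", "diameter")) {
  stopifnot(inherits(ds, "dwi_dataset"))
  if (ds$domain != "complex")
    stop("phase estimation requires complex-domain input")
  convention <- match.arg(convention)
  r_half <- if (convention == "radius") filter_fwhm_fraction
            else filter_fwhm_fraction / 2
  d <- dim(ds$data)
  nx <- d[1]; ny <- d[2]

  # normalised frequency radius, DC at [1,1] (unshifted FFT layout)
  fr <- function(n) {
    k <- 0:(n - 1)
    kk <- ifelse(k > n / 2, k - n, k)
    kk / (n / 2)
  }
  r <- sqrt(outer(fr(nx)^2, fr(ny)^2, `+`))
  r1 <- max(r_half - taper / 2, 0)
  r2 <- r_half + taper / 2
  W <- ifelse(r <= r1, 1,
       ifelse(r >= r2, 0, 0.5 * (1 + cos(pi * (r - r1) / (r2 - r1)))))

  phase <- array(0, d)
  for (v in seq_len(d[4])) for (z in seq_len(d[3])) {
    sl <- ds$data[, , z, v]
    sm <- fft(fft(sl) * W, inverse = TRUE)  # scale irrelevant for Arg
    phase[, , z, v] <- Arg(sm)
  }
  structure(list(phase = phase,
                 filter_fwhm_fraction = filter_fwhm_fraction,
                 taper = taper, convention = convention),
            class = "phase_field")
}

#' Exact phase field of a phantom
#'
#' Wraps the generator's true per-slice, per-volume phase into a
#' `phase_field`, so phantom evaluations can rotate with the exact phase and
#' isolate domain effects (noise floor, rectification) from phase-estimation
#' error.  With an estimated phase, zero-signal regions retain a partial
#' noise floor because the low-passed phase there follows the noise itself;
#' the exact field removes that confound.
#'
#' @param gt a `phantom_gt`.
#' @return a `phase_field`.
#' @export
true_phase_field <- function(gt) {
  stopifnot(inherits(gt, "phantom_gt"))
  structure(list(phase = gt$phase_field, filter_fwhm_fraction = NA_real_,
                 taper = NA_real_, convention = "exact"),
            class = "phase_field")
}

#' Rotate complex data to the real axis
#'
#' Multiplies the complex data by the conjugate phase and keeps the real
#' channel.  With an exact phase field the result carries the signal plus
#' zero-mean Gaussian noise, so the rectified noise floor of the magnitude
#' is absent; the imaginary channel (noise only, under exact phase) is
#' discarded unless `keep_imaginary`.
#'
#' @param ds a complex-domain `dwi_dataset`.
#' @param pf a `phase_field` with matching geometry.
#' @param keep_imaginary if TRUE the imaginary channel is returned in the
#'   `imaginary` attribute for diagnostics.
#' @return a `dwi_dataset` with `domain = "real_rotated"`.
#' @export
rotate_to_real <- function(ds, pf, keep_imaginary = FALSE) {
  stopifnot(inherits(ds, "dwi_dataset"), inherits(pf, "phase_field"))
  if (ds$domain != "complex") stop("rotation requires complex-domain input")
  if (!all(dim(ds$data) == dim(pf$phase)))
    stop("phase field geometry does not match the dataset")
  rot <- ds$data * exp(-1i * pf$phase)
  re <- Re(rot); dim(re) <- dim(ds$data)
  out <- dwi_dataset(re, ds$grad, ds$voxel_size, "real_rotated", ds$sigma_map)
  if (keep_imaginary) {
    im <- Im(rot); dim(im) <- dim(ds$data)
    attr(out, "imaginary") <- im
  }
  out
}

check_aligned <- function(repeats, domain) {
  stopifnot(length(repeats) >= 1L)
  for (r in repeats) {
    stopifnot(inherits(r, "dwi_dataset"))
    if (r$domain != domain)
      stop(sprintf("expected %s-domain repeats, got %s", domain, r$domain))
  }
  d1 <- dim(repeats[[1]]$data)
  b1 <- repeats[[1]]$grad$bvals
  for (r in repeats[-1]) {
    if (!all(dim(r$data) == d1) || !isTRUE(all.equal(r$grad$bvals, b1)))
      stop("repeats must share geometry and gradient table")
  }
  invisible(TRUE)
}

#' Complex (real-valued) average of aligned repeats
#'
#' Voxelwise arithmetic mean of real-rotated repeats.  Zero-mean Gaussian
#' noise averages out (std shrinks by sqrt(R)) while the signal is preserved,
#' so the average is an unbiased low-noise reference free of the magnitude
#' noise floor.
#'
#' @param repeats list of `dwi_dataset`s with `domain = "real_rotated"`.
#' @return a real-rotated `dwi_dataset`.
#' @export
complex_average <- function(repeats) {
  check_aligned(repeats, "real_rotated")
  acc <- Reduce(`+`, lapply(repeats, function(r) r$data)) / length(repeats)
  r1 <- repeats[[1]]
  dwi_dataset(acc, r1$grad, r1$voxel_size, "real_rotated", r1$sigma_map)
}

#' Magnitude average of aligned repeats
#'
#' Voxelwise mean of magnitudes.  Averaging after the modulus preserves the
#' Rician/Rayleigh noise floor: in a zero-signal region the mean stays at
#' sigma * sqrt(pi/2) no matter how many repeats are averaged.
#'
#' @param repeats list of `dwi_dataset`s with `domain = "magnitude"`.
#' @return a magnitude-domain `dwi_dataset`.
#' @export
magnitude_average <- function(repeats) {
  check_aligned(repeats, "magnitude")
  acc <- Reduce(`+`, lapply(repeats, function(r) r$data)) / length(repeats)
  r1 <- repeats[[1]]
  dwi_dataset(acc, r1$grad, r1$voxel_size, "magnitude", r1$sigma_map)
}
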