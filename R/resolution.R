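#' Gaussian smoothing of a 3-D volume
#'
#' `"spectral"` multiplies the 3-D FFT by the exact Gaussian transfer
#' function (periodic boundaries): the resulting autocorrelation is exactly
#' Gaussian at the requested width, which makes it the forward oracle for
#' the FWHM estimator.  `"kernel"` is separable spatial convolution with a
#' truncated sampled kernel and renormalised edges (no wrap-around).
#'
#' @param vol 3-D array.
#' @param fwhm_vox per-axis FWHM in voxels (scalar recycled).
#' @param method `"spectral"` or `"kernel"`.
#' @return smoothed 3-D array.
#' @export
gaussian_smooth_volume <- function(vol, fwhm_vox,
                                   method = c("spectral", "kernel")) {
  method <- match.arg(method)
  d <- dim(vol)
  stopifnot(length(d) == 3L)
  fwhm_vox <- rep(fwhm_vox, length.out = 3)
  sig <- fwhm_vox / sqrt(8 * log(2))
  if (method == "kernel")
    return(array(.smooth3d_cpp(as.vector(vol), as.integer(d), sig), d))
  freq <- function(n) {
    k <- 0:(n - 1)
    ifelse(k > n / 2, k - n, k) / n
  }
  tf <- exp(-2 * pi^2 * (
    outer(outer(sig[1]^2 * freq(d[1])^2, sig[2]^2 * freq(d[2])^2, `+`),
          sig[3]^2 * freq(d[3])^2, `+`)))
  Re(fft(fft(vol) * tf, inverse = TRUE)) / prod(d)
}

#' Standardized model residuals
#'
#' `residual = data - prediction`, standardized per volume to zero mean and
#' unit variance within the mask.  Volumes whose in-mask residuals have zero
#' variance (e.g. an exact fit) are flagged degenerate and left at zero.
#'
#' @param ds a `dwi_dataset`.
#' @param prediction 4-D model prediction on the same volumes.
#' @param mask 3-D logical mask.
#' @return 4-D standardized residual field (zero outside the mask);
#'   attribute `"degenerate"` flags all-zero volumes.
#' @export
standardized_residuals <- function(ds, prediction, mask) {
  data <- if (inherits(ds, "dwi_dataset")) ds$data else ds
  stopifnot(all(dim(data) == dim(prediction)))
  d <- dim(data)
  r <- data - prediction
  degen <- logical(d[4])
  mv <- as.vector(mask)
  for (v in seq_len(d[4])) {
    sl <- r[, , , v]
    x <- sl[mv]
    s <- sd(x)
    if (s == 0) { degen[v] <- TRUE; sl[] <- 0 }
    else sl <- (sl - mean(x)) / s
    sl[!mv] <- 0
    r[, , , v] <- sl
  }
  attr(r, "degenerate") <- degen
  r
}

fwhm_one_axis <- function(field, mask, axis, delta, method) {
  d <- dim(field)
  n <- d[axis]
  idx_lo <- lapply(seq_len(3), function(a)
    if (a == axis) seq_len(n - 1) else seq_len(d[a]))
  idx_hi <- lapply(seq_len(3), function(a)
    if (a == axis) 2:n else seq_len(d[a]))
  a <- do.call(`[`, c(list(field), idx_lo))
  b <- do.call(`[`, c(list(field), idx_hi))
  ma <- do.call(`[`, c(list(mask), idx_lo))
  mb <- do.call(`[`, c(list(mask), idx_hi))
  ok <- ma & mb
  v0 <- var(field[mask])
  if (method == "derivative_variance") {
    vi <- var((b - a)[ok])
    ratio <- vi / (2 * v0)
    if (!is.finite(ratio) || ratio <= 0 || ratio >= 1)
      return(c(NA_real_, 1))
    s2 <- -delta^2 / (4 * log(1 - ratio))
    c(sqrt(8 * log(2)) * sqrt(s2), 0)
  } else {                                   # acf_lag1
    # For a Gaussian kernel of width sigma, rho(dx) = exp(-dx^2/(4 sigma^2)),
    # so FWHM = dx sqrt(-2 ln 2 / ln rho1) recovers the *kernel* FWHM (the
    # ACF itself is sqrt(2) wider than the kernel).
    rho <- cor(a[ok], b[ok])
    if (!is.finite(rho) || rho <= 0 || rho >= 1) return(c(NA_real_, 1))
    c(delta * sqrt(-2 * log(2) / log(rho)), 0)
  }
}

#' Effective resolution (FWHM) from standardized residuals
#'
#' Per axis i, the variance of adjacent-voxel differences `v_i` relative to
#' the field variance `v0` identifies the Gaussian kernel whose smoothing
#' would produce the observed spatial autocorrelation:
#' `sigma_i^2 = -dx_i^2 / (4 ln(1 - v_i / (2 v0)))` and
#' `FWHM_i = sigma_i sqrt(8 ln 2)` (the `"derivative_variance"` method; the
#' `"acf_lag1"` cross-check uses `FWHM_i = dx_i sqrt(-2 ln 2 / ln rho_1)`,
#' which is the same relation expressed through the lag-1 autocorrelation).
#' Per-volume estimates are aggregated across volumes.  Voxel pairs whose
#' forward neighbour leaves the mask are excluded.
#'
#' @param residuals 4-D standardized residual field (>= 10 volumes).
#' @param mask 3-D logical mask.
#' @param voxel_size length-3 voxel edge lengths (mm).
#' @param method `"derivative_variance"` (default) or `"acf_lag1"`.
#' @param aggregate `"mean"` (default) or `"median"` across volumes.
#' @return object of class `smoothness_estimate`: `fwhm_mm`, `fwhm_vox`
#'   (per-axis, ordered x, y, z), `n_volumes_used`, `method`,
#'   `low_confidence` (TRUE when >= 50% of volumes hit the formula's clip).
#' @export
estimate_fwhm <- function(residuals, mask, voxel_size,
                          method = c("derivative_variance", "acf_lag1"),
                          aggregate = c("mean", "median")) {
  method <- match.arg(method)
  aggregate <- match.arg(aggregate)
  d <- dim(residuals)
  stopifnot(length(d) == 4L)
  if (d[4] < 10L) stop("need at least 10 volumes of residuals")
  est <- array(NA_real_, c(d[4], 3))
  clipped <- matrix(0, d[4], 3)
  for (v in seq_len(d[4])) {
    f <- residuals[, , , v]
    for (ax in 1:3) {
      r <- fwhm_one_axis(f, mask, ax, voxel_size[ax], method)
      est[v, ax] <- r[1]
      clipped[v, ax] <- r[2]
    }
  }
  agg <- if (aggregate == "mean") function(x) mean(x, na.rm = TRUE)
         else function(x) median(x, na.rm = TRUE)
  fwhm_mm <- apply(est, 2, agg)
  frac_clip <- colMeans(clipped)
  low_conf <- any(frac_clip >= 0.5)
  if (low_conf)
    warning("FWHM formula argument clipped in >= 50% of volumes; estimate is low-confidence")
  structure(list(fwhm_mm = fwhm_mm, fwhm_vox = fwhm_mm / voxel_size,
                 n_volumes_used = d[4], method = method,
                 clip_fraction = frac_clip, low_confidence = low_conf),
            class = "smoothness_estimate")
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat(sprintf("<smoothness_estimate> FWHM (mm): %s; (vox): %s [%s, %d volumes]\n",
              paste(signif(x$fwhm_mm, 4), collapse = ", "),
              paste(signif(x$fwhm_vox, 4), collapse = ", "),
              x$method, x$n_volumes_used))
  invisible(x)
}

#' Denoising resolution penalty
#'
#' `100 * (FWHM_denoised - FWHM_raw) / FWHM_raw` per axis: the percentage of
#' effective resolution lost (positive = blurring) by a denoiser.
#'
#' @param raw,denoised `smoothness_estimate`s on matching axes.
#' @return numeric length-3 percent change (x, y, z).
#' @export
resolution_penalty <- function(raw, denoised) {
  stopifnot(inherits(raw, "smoothness_estimate"),
            inherits(denoised, "smoothness_estimate"))
  100 * (denoised$fwhm_mm - raw$fwhm_mm) / raw$fwhm_mm
}

#' Patch-size sweep: resolution penalty vs CNR gain
#'
#' For each patch size: denoise, fit the diffusion tensor to the chosen
#' shell, estimate the residual FWHM penalty relative to raw, and the
#' in-mask median angular CNR gain.  Rows are flagged when the size equals
#' the method's default patch rule.
#'
#' @param ds a `dwi_dataset` (magnitude or real-rotated).
#' @param method `"mppca"` or `"nordic"`.
#' @param sizes vector of odd patch edges; all must fit the image.
#' @param mask 3-D logical evaluation mask.
#' @param shell_b shell used for the DTI fit and the CNR (default 1000).
#' @param stride patch stride (larger strides trade accuracy for speed).
#' @param noise_map sigma map, required for `"nordic"`.
#' @param seed seed for the NORDIC threshold Monte Carlo.
#' @return data.frame: size, per-axis FWHM and penalty (%), median CNR,
#'   CNR gain (%), `is_default`.
#' @export
patch_size_sweep <- function(ds, method = c("mppca", "nordic"), sizes, mask,
                             shell_b = 1000, stride = 1L, noise_map = NULL,
                             seed = 1L) {
  method <- match.arg(method)
  stopifnot(all(sizes %% 2 == 1))
  fit_raw <- fit_dti(ds, shell_b = shell_b, mask = mask)
  res_raw <- standardized_residuals(ds$data[, , , fit_raw$volumes, drop = FALSE],
                                    predict_dti(fit_raw), mask)
  fwhm_raw <- estimate_fwhm(res_raw, mask, ds$voxel_size)
  cnr_raw <- median(angular_cnr(ds, shell_b, mask), na.rm = TRUE)
  p_def <- default_patch_size(n_volumes(ds), method)

  rows <- lapply(sizes, function(P) {
    ps <- patch_spec(P, stride = min(stride, P))
    den <- if (method == "mppca") mppca_denoise(ds, ps)$denoised
           else nordic_denoise(ds, ps, noise_map = noise_map,
                               seed = seed)$denoised
    fit <- fit_dti(den, shell_b = shell_b, mask = mask)
    res <- standardized_residuals(den$data[, , , fit$volumes, drop = FALSE],
                                  predict_dti(fit), mask)
    fw <- estimate_fwhm(res, mask, ds$voxel_size)
    pen <- resolution_penalty(fwhm_raw, fw)
    cnr <- median(angular_cnr(den, shell_b, mask), na.rm = TRUE)
    data.frame(size = P,
               fwhm_x = fw$fwhm_mm[1], fwhm_y = fw$fwhm_mm[2],
               fwhm_z = fw$fwhm_mm[3],
               penalty_x = pen[1], penalty_y = pen[2], penalty_z = pen[3],
               cnr = cnr, cnr_gain_pct = 100 * (cnr - cnr_raw) / cnr_raw,
               is_default = P == p_def)
  })
  out <- do.call(rbind, rows)
  attr(out, "raw") <- list(fwhm = fwhm_raw, cnr = cnr_raw)
  out
}
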