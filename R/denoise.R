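#' Patch specification
#'
#' @param size odd integer >= 3; isotropic patch edge in voxels.
#' @param stride patch step in voxels (1 = fully overlapping).
#' @param aggregation how overlapping patch estimates combine: `"average"`
#'   (unweighted mean over all patches covering a voxel) or `"center_only"`.
#' @return object of class `patch_spec`.
#' @export
patch_spec <- function(size, stride = 1L,
                       aggregation = c("average", "center_only")) {
  size <- as.integer(size); stride <- as.integer(stride)
  if (size < 3L || size %% 2L == 0L) stop("patch size must be odd and >= 3")
  if (stride < 1L || stride > size) stop("stride must be in [1, size]")
  structure(list(size = size, stride = stride,
                 aggregation = match.arg(aggregation)),
            class = "patch_spec")
}

#' Default patch size for a given volume count
#'
#' MP-PCA implementations take the smallest odd patch edge P with
#' P^3 >= N (N = number of volumes); NORDIC-style denoisers keep an 11:1
#' ratio of patch voxels to volumes, P^3 >= 11 N.
#'
#' @param n_volumes number of volumes denoised jointly.
#' @param method `"mppca"` or `"nordic"`.
#' @return odd integer patch edge.
#' @export
default_patch_size <- function(n_volumes, method = c("mppca", "nordic")) {
  method <- match.arg(method)
  stopifnot(n_volumes >= 1)
  target <- if (method == "mppca") n_volumes else 11 * n_volumes
  P <- 3L
  while (P^3 < target) P <- P + 2L
  P
}

#' Marchenko-Pastur rank and noise-variance selection
#'
#' Given the descending eigenvalues of the scaled covariance `X'X / M` of an
#' M x N patch Casorati matrix, finds the signal rank p whose trailing
#' N - p eigenvalues are consistent with the Marchenko-Pastur bulk: with
#' `sigma2(p) = mean of the trailing eigenvalues`, p is accepted when
#' `lambda_{p+1} - lambda_N <= 4 sigma2(p) sqrt((N - p) / M)` (the bulk width
#' of an MP spectrum with aspect ratio (N-p)/M).
#'
#' @param eigenvalues numeric vector, non-increasing, non-negative.
#' @param M voxels per patch.
#' @param N volumes (length of `eigenvalues`).
#' @return object of class `mp_result` with fields `eigenvalues`, `rank`,
#'   `sigma2`, `M`, `N`, `gamma`.
#' @export
mp_threshold <- function(eigenvalues, M, N = length(eigenvalues)) {
  eigenvalues <- as.numeric(eigenvalues)
  if (length(eigenvalues) != N) stop("N must equal length(eigenvalues)")
  if (any(diff(eigenvalues) > 1e-10 * max(abs(eigenvalues), 1)))
    stop("eigenvalues must be sorted in non-increasing order")
  if (any(eigenvalues < -1e-12)) stop("eigenvalues must be non-negative")
  res <- .mp_rank_cpp(pmax(eigenvalues, 0), M, N)
  structure(list(eigenvalues = eigenvalues, rank = res$rank,
                 sigma2 = res$sigma2, M = M, N = N, gamma = N / M),
            class = "mp_result")
}

#' @export
print.mp_result <- function(x, ...) {
  cat(sprintf("<mp_result> M=%d N=%d rank=%d sigma2=%.4g\n",
              x$M, x$N, x$rank, x$sigma2))
  invisible(x)
}

resolve_patch <- function(ds, patch, method) {
  if (is.null(patch))
    patch <- patch_spec(default_patch_size(n_volumes(ds), method))
  stopifnot(inherits(patch, "patch_spec"))
  patch
}

#' MP-PCA patch denoising
#'
#' Denoises all volumes jointly.  For every patch the M x N Casorati matrix
#' (M = P^3 voxels, N volumes, no mean removal by default) is
#' eigen-decomposed, components beyond the Marchenko-Pastur rank are zeroed,
#' and the patch is reconstructed; overlapping estimates combine per the
#' patch aggregation rule.  Works identically on magnitude data (|MPPCA|)
#' and on complex data rotated to the real axis (MPPCA*) -- the input domain
#' is what distinguishes the two variants.
#'
#' @param ds a `dwi_dataset` with domain `"magnitude"` or `"real_rotated"`.
#' @param patch a [patch_spec()]; defaults to the MP-PCA patch rule.
#' @param demean if TRUE, per-volume patch means are removed before the
#'   eigendecomposition and restored afterwards.
#' @return list with `denoised` (a `dwi_dataset`), `sigma_map` (aggregated
#'   per-voxel noise sigma estimate) and `rank_map` (aggregated signal rank).
#' @export
mppca_denoise <- function(ds, patch = NULL, demean = FALSE) {
  stopifnot(inherits(ds, "dwi_dataset"))
  if (!ds$domain %in% c("magnitude", "real_rotated"))
    stop("MP-PCA operates on magnitude or real-rotated data; rotate complex data first")
  patch <- resolve_patch(ds, patch, "mppca")
  d <- dim(ds$data)
  res <- .patch_engine_cpp(as.vector(ds$data), as.integer(d), patch$size,
                           patch$stride,
                           if (patch$aggregation == "center_only") 1L else 0L,
                           0L, 0, numeric(0), demean)
  den <- array(res$denoised, d)
  if (ds$domain == "magnitude") den[den < 0] <- 0
  list(denoised = dwi_dataset(den, ds$grad, ds$voxel_size, ds$domain,
                              ds$sigma_map),
       sigma_map = array(res$sigma, d[1:3]),
       rank_map = array(res$rank, d[1:3]))
}

#' Monte-Carlo singular-value threshold for unit-variance noise
#'
#' Mean, over `n_mc` seeded draws, of the largest singular value of an
#' M x N matrix with i.i.d. standard Gaussian entries.  This is the hard
#' threshold a variance-normalised patch must exceed to be counted as
#' signal.
#'
#' @param M,N Casorati matrix dimensions.
#' @param n_mc number of Monte-Carlo draws.
#' @param seed integer seed (deterministic threshold given the seed).
#' @return scalar threshold.
#' @export
nordic_threshold <- function(M, N, n_mc = 100L, seed = 1L) {
  set.seed(seed)
  vals <- vapply(seq_len(n_mc), function(i) {
    X <- matrix(rnorm(M * N), M, N)
    sqrt(max(eigen(crossprod(X), symmetric = TRUE,
                   only.values = TRUE)$values))
  }, numeric(1))
  mean(vals)
}

#' NORDIC-style variance-normalised patch denoising
#'
#' Divides the data voxelwise by a noise sigma map so the noise is
#' unit-variance everywhere (restoring the stationarity the threshold
#' requires), then hard-thresholds the singular values of every patch
#' Casorati matrix at the Monte-Carlo largest singular value of a pure-noise
#' matrix of the same size, reconstructs, and multiplies the sigma map back.
#'
#' @param ds a `dwi_dataset` with domain `"real_rotated"` (complex data
#'   should be rotated to the real axis first).
#' @param patch a [patch_spec()]; defaults to the NORDIC 11:1 patch rule.
#' @param noise_map 3-D noise sigma map, strictly positive (see
#'   [estimate_noise_map()]); defaults to `ds$sigma_map`.
#' @param n_mc,seed Monte-Carlo settings for the threshold.
#' @return list with `denoised` (a `dwi_dataset`), `sigma_map` (residual
#'   noise sigma estimate, in signal units of the normalised data) and
#'   `rank_map` (retained singular values per patch).
#' @export
nordic_denoise <- function(ds, patch = NULL, noise_map = ds$sigma_map,
                           n_mc = 100L, seed = 1L) {
  stopifnot(inherits(ds, "dwi_dataset"))
  if (ds$domain == "complex")
    stop("rotate complex data to the real axis before NORDIC denoising")
  if (ds$domain == "magnitude")
    stop("NORDIC operates on real-rotated (complex-domain) data")
  if (is.null(noise_map)) stop("a noise sigma map is required")
  d <- dim(ds$data)
  stopifnot(all(dim(noise_map) == d[1:3]))
  if (any(noise_map <= 0))
    stop("noise_map must be strictly positive everywhere it is used")
  patch <- resolve_patch(ds, patch, "nordic")
  M <- patch$size^3
  tau <- nordic_threshold(M, d[4], n_mc = n_mc, seed = seed)
  res <- .patch_engine_cpp(as.vector(ds$data), as.integer(d), patch$size,
                           patch$stride,
                           if (patch$aggregation == "center_only") 1L else 0L,
                           1L, tau, as.vector(noise_map), FALSE)
  list(denoised = dwi_dataset(array(res$denoised, d), ds$grad, ds$voxel_size,
                              ds$domain, ds$sigma_map),
       sigma_map = array(res$sigma, d[1:3]),
       rank_map = array(res$rank, d[1:3]),
       threshold = tau)
}

#' Estimate a noise sigma map
#'
#' Default (`"b0"`): per-voxel standard deviation across the b = 0 volumes,
#' smoothed with a small Gaussian kernel (the b=0 signal is constant across
#' volumes, so the variation is noise).  Alternative (`"mppca"`): the
#' sigma map aggregated from an MP-PCA pass.
#'
#' @param ds a `dwi_dataset` (any real-valued domain).
#' @param method `"b0"` or `"mppca"`.
#' @param smooth_fwhm_vox FWHM (voxels) of the smoothing kernel for `"b0"`.
#' @return 3-D sigma map with the method recorded in the `"method"` attribute.
#' @export
estimate_noise_map <- function(ds, method = c("b0", "mppca"),
                               smooth_fwhm_vox = 3) {
  stopifnot(inherits(ds, "dwi_dataset"))
  method <- match.arg(method)
  d <- dim(ds$data)
  if (method == "mppca") {
    sm <- mppca_denoise(ds)$sigma_map
    attr(sm, "method") <- "mppca"
    return(sm)
  }
  b0 <- b0_indices(ds$grad)
  if (length(b0) < 2L)
    stop("need at least 2 b=0 volumes (or use method = 'mppca')")
  x <- ds$data[, , , b0, drop = FALSE]
  if (is.complex(x)) x <- Mod(x)
  mu <- apply(x, 1:3, mean)
  sdmap <- sqrt(apply(x, 1:3, var))
  sig <- smooth_fwhm_vox / sqrt(8 * log(2))
  sm <- array(.smooth3d_cpp(as.vector(sdmap), as.integer(d[1:3]),
                            rep(sig, 3)), d[1:3])
  attr(sm, "method") <- "b0"
  attr(sm, "b0_mean") <- mu
  sm
}

#' Non-local means denoising of a single volume
#'
#' Classical NLM: every voxel becomes the weighted mean of the voxels in its
#' search window, with weights
#' `w = exp(-max(d^2 - 2 sigma^2, 0) / h^2)` where `d^2` is the mean squared
#' difference between the two local patches and `h = h_factor * sigma`.
#' A constant image, or the limit `sigma -> 0`, returns the input.
#'
#' @param volume 3-D image array.
#' @param sigma noise standard deviation (signal units), > 0.
#' @param patch_radius patch half-width (patch edge `2r+1`).
#' @param search_radius search-window half-width.
#' @param h_factor filtering strength relative to sigma.
#' @return denoised 3-D array.
#' @export
nlm_denoise <- function(volume, sigma, patch_radius = 1L, search_radius = 5L,
                        h_factor = 1) {
  stopifnot(length(dim(volume)) == 3L, sigma > 0)
  out <- .nlm_cpp(as.vector(volume), as.integer(dim(volume)), sigma,
                  as.integer(patch_radius), as.integer(search_radius),
                  h_factor * sigma)
  array(out, dim(volume))
}

#' Non-local means over all volumes of a dataset
#'
#' Applies [nlm_denoise()] independently to each volume (NLM carries no
#' inter-volume model).
#'
#' @param ds a magnitude-domain `dwi_dataset`.
#' @param sigma scalar noise sigma; defaults to the median of `ds$sigma_map`.
#' @inheritParams nlm_denoise
#' @return a denoised `dwi_dataset`.
#' @export
nlm_denoise_dataset <- function(ds, sigma = NULL, patch_radius = 1L,
                                search_radius = 5L, h_factor = 1) {
  stopifnot(inherits(ds, "dwi_dataset"))
  if (is.null(sigma)) {
    if (is.null(ds$sigma_map)) stop("provide sigma or a dataset sigma_map")
    sigma <- median(ds$sigma_map)
  }
  d <- dim(ds$data)
  out <- ds$data
  for (v in seq_len(d[4]))
    out[, , , v] <- nlm_denoise(ds$data[, , , v], sigma, patch_radius,
                                search_radius, h_factor)
  dwi_dataset(out, ds$grad, ds$voxel_size, ds$domain, ds$sigma_map)
}
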