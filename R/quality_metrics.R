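#' Real even spherical-harmonic design matrix
#'
#' Orthonormal real spherical harmonics of even degree only (the diffusion
#' signal is antipodally symmetric): for degree l and order m,
#' `m = 0` uses `N_l0 P_l0(cos theta)`, `m > 0` uses
#' `sqrt(2) N_lm P_lm cos(m phi)` and `m < 0` uses
#' `sqrt(2) N_l|m| P_l|m| sin(|m| phi)`, with
#' `N_lm = sqrt((2l+1)/(4 pi) (l-m)!/(l+m)!)`.  With this normalisation a
#' constant attenuation `a` fits as `c_00 = a sqrt(4 pi)`.
#'
#' @param dirs n x 3 matrix of unit direction vectors.
#' @param order maximum even degree L.
#' @return n x k design matrix with attribute `"l"` giving the degree of
#'   each column; k = (L+1)(L+2)/2.
#' @export
sh_basis <- function(dirs, order = 8L) {
  stopifnot(order %% 2 == 0, ncol(dirs) == 3L)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  ct <- pmin(pmax(dirs[, 3], -1), 1)
  phi <- atan2(dirs[, 2], dirs[, 1])
  n <- nrow(dirs)
  ls <- seq(0, order, by = 2)
  k <- (order + 1) * (order + 2) / 2
  B <- matrix(0, n, k)
  ldeg <- integer(k)
  col <- 1L
  for (l in ls) {
    # pracma::legendre returns (l+1) x n matrix of P_l^m, m = 0..l, with
    # the Condon-Shortley phase (MATLAB convention)
    P <- pracma::legendre(l, ct)
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
    for (m in -l:l) {
      am <- abs(m)
      Nlm <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      # undo the Condon-Shortley phase so the basis matches the standard
      # real SH convention
      Plm <- P[am + 1, ] * (-1)^am
      B[, col] <- if (m == 0) Nlm * Plm
                  else if (m > 0) sqrt(2) * Nlm * Plm * cos(m * phi)
                  else sqrt(2) * Nlm * Plm * sin(am * phi)
      ldeg[col] <- as.integer(l)
      col <- col + 1L
    }
  }
  attr(B, "l") <- ldeg
  B
}

largest_feasible_order <- function(n_dirs, order) {
  while (order > 0 && (order + 1) * (order + 2) / 2 > n_dirs)
    order <- order - 2L
  as.integer(order)
}

#' Least-squares spherical-harmonic fit of shell attenuation
#'
#' Fits the real even SH basis to per-voxel signal attenuation (shell signal
#' divided by the mean b=0 signal) by unregularised least squares.  If the
#' shell has fewer directions than coefficients the order is reduced to the
#' largest feasible even order (with a warning).
#'
#' @param attenuation numeric vector (one voxel) or matrix (voxels x
#'   directions) of finite attenuation values.
#' @param bvecs n_dirs x 3 matrix of shell directions.
#' @param order maximum even SH degree; default 8.
#' @param lambda optional Laplace-Beltrami regularisation weight (0 = off,
#'   the default, so that exact linear recovery holds).
#' @return object of class `sh_fit` with `coeffs` (voxels x k), `order`,
#'   `l` (degree per column) and `design_cond`.
#' @export
fit_sh <- function(attenuation, bvecs, order = 8L, lambda = 0) {
  if (is.null(dim(attenuation))) attenuation <- matrix(attenuation, 1)
  n_dirs <- ncol(attenuation)
  stopifnot(nrow(bvecs) == n_dirs)
  if (any(!is.finite(attenuation))) stop("attenuation must be finite")
  ord <- largest_feasible_order(n_dirs, order)
  if (ord < order)
    warning(sprintf("order reduced from %d to %d (%d directions)",
                    order, ord, n_dirs))
  B <- sh_basis(bvecs, ord)
  G <- crossprod(B)
  if (lambda > 0) {
    l <- attr(B, "l")
    G <- G + lambda * diag(l^2 * (l + 1)^2)
  }
  coeffs <- t(solve(G, t(attenuation %*% B)))
  structure(list(coeffs = coeffs, order = ord, l = attr(B, "l"),
                 design_cond = kappa(B, exact = TRUE)),
            class = "sh_fit")
}

#' Angular power per spherical-harmonic order
#'
#' `P_l = sum_m c_lm^2` for each even degree l of the fit.
#'
#' @param fit an `sh_fit`.
#' @return matrix (voxels x orders) of non-negative powers; column names are
#'   the degrees 0, 2, ..., L.
#' @export
sh_power <- function(fit) {
  stopifnot(inherits(fit, "sh_fit"))
  ls <- seq(0, fit$order, by = 2)
  P <- vapply(ls, function(l)
    rowSums(fit$coeffs[, fit$l == l, drop = FALSE]^2),
    numeric(nrow(fit$coeffs)))
  if (is.null(dim(P))) P <- matrix(P, nrow = 1)
  colnames(P) <- ls
  P
}

#' Voxelwise SNR map from b=0 repeats
#'
#' Per voxel: mean across the b = 0 volumes divided by their standard
#' deviation (denominator with n-1 degrees of freedom).  Zero-variance
#' voxels are reported at `cap` and flagged.
#'
#' @param ds a `dwi_dataset` with at least 3 b=0 volumes.
#' @param mask optional 3-D logical mask; outside voxels are NA.
#' @param cap value assigned to degenerate zero-variance voxels.
#' @return 3-D SNR map; attribute `"capped"` is the logical map of
#'   degenerate voxels.
#' @export
snr_map <- function(ds, mask = NULL, cap = 1e6) {
  stopifnot(inherits(ds, "dwi_dataset"))
  b0 <- b0_indices(ds$grad)
  if (length(b0) < 3L) stop("SNR map needs at least 3 b=0 volumes")
  x <- ds$data[, , , b0, drop = FALSE]
  if (is.complex(x)) x <- Mod(x)
  mu <- apply(x, 1:3, mean)
  s <- apply(x, 1:3, sd)
  capped <- s == 0
  snr <- mu / s
  snr[capped] <- cap
  if (!is.null(mask)) snr[!mask] <- NA_real_
  attr(snr, "capped") <- capped
  snr
}

#' Angular contrast-to-noise ratio map for one shell
#'
#' Fits the spherical-harmonic angular predictor to the shell signal and
#' forms, per voxel, the ratio of angular contrast variance to noise
#' variance.  The noise variance is the residual variance of the SH fit with
#' a degrees-of-freedom-corrected denominator (n_dirs - n_coeffs); the
#' contrast is the variance of the predicted signal across directions,
#' bias-corrected by `sigma2 (k - 1)/(n - 1)` so pure noise scores ~0, and
#' clipped at zero.  Zero-residual (noiseless) voxels report `cap`.
#'
#' @param ds a `dwi_dataset`.
#' @param shell_b nominal b-value of the shell (needs >= 15 directions).
#' @param mask optional 3-D logical mask.
#' @param order maximum even SH degree for the predictor (reduced
#'   automatically when the shell has too few directions).
#' @param cap value assigned to zero-residual voxels.
#' @return 3-D CNR map (NA outside the mask).
#' @export
angular_cnr <- function(ds, shell_b, mask = NULL, order = 6L, cap = 1e6) {
  stopifnot(inherits(ds, "dwi_dataset"))
  idx <- shell_indices(ds, shell_b)
  if (length(idx) < 15L)
    stop(sprintf("shell b=%g has %d directions; need >= 15", shell_b,
                 length(idx)))
  d <- dim(ds$data)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  n <- length(idx)
  # keep a residual dof margin of at least 5 directions
  ord <- largest_feasible_order(n - 5L, order)
  B <- sh_basis(ds$grad$bvecs[idx, , drop = FALSE], ord)
  k <- ncol(B)
  y <- matrix(ds$data[, , , idx], prod(d[1:3]), n)[as.vector(mask), ,
                                                   drop = FALSE]
  if (is.complex(y)) y <- Mod(y)
  H <- B %*% solve(crossprod(B), t(B))
  fitted <- y %*% t(H)
  resid <- y - fitted
  sigma2 <- rowSums(resid^2) / (n - k)
  vfit <- apply(fitted, 1, var)
  contrast <- pmax(vfit - sigma2 * (k - 1) / (n - 1), 0)
  cnr <- ifelse(sigma2 <= .Machine$double.eps^0.5 * apply(y, 1, function(r)
    max(mean(r^2), 1)), cap, contrast / sigma2)
  out <- array(NA_real_, d[1:3])
  out[mask] <- cnr
  out
}

shell_attenuation <- function(ds, shell_b, mask) {
  d <- dim(ds$data)
  idx <- shell_indices(ds, shell_b)
  b0 <- b0_indices(ds$grad)
  x <- ds$data
  if (is.complex(x)) x <- Mod(x)
  nv <- prod(d[1:3])
  b0m <- rowMeans(matrix(x[, , , b0], nv, length(b0)))
  y <- matrix(x[, , , idx], nv, length(idx))
  keep <- as.vector(mask) & b0m > 0
  list(att = y[keep, , drop = FALSE] / b0m[keep],
       bvecs = ds$grad$bvecs[idx, , drop = FALSE], keep = keep)
}

#' Percent change in spherical-harmonic power after denoising
#'
#' Fits SH to the shell attenuation (signal over the mean b=0 volume) of
#' both datasets and reports, per even order,
#' `100 * (mean_mask P_l(denoised) - mean_mask P_l(raw)) / mean_mask P_l(raw)`.
#'
#' @param raw,denoised `dwi_dataset`s sharing the gradient table.
#' @param mask 3-D logical mask over which powers are averaged.
#' @param shell_b shell to analyse.
#' @param order maximum even SH degree; default 8.
#' @return named numeric vector of percent changes per order.
#' @export
power_change <- function(raw, denoised, mask, shell_b, order = 8L) {
  stopifnot(isTRUE(all.equal(raw$grad$bvals, denoised$grad$bvals)))
  ar <- shell_attenuation(raw, shell_b, mask)
  ad <- shell_attenuation(denoised, shell_b, mask)
  pr <- colMeans(sh_power(fit_sh(ar$att, ar$bvecs, order)))
  pd <- colMeans(sh_power(fit_sh(ad$att, ad$bvecs, order)))
  100 * (pd - pr) / pr
}
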