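dti_design <- function(bvals, bvecs) {
  g <- bvecs
  cbind(1,
        -bvals * g[, 1]^2, -bvals * g[, 2]^2, -bvals * g[, 3]^2,
        -2 * bvals * g[, 1] * g[, 2],
        -2 * bvals * g[, 1] * g[, 3],
        -2 * bvals * g[, 2] * g[, 3])
}

#' Diffusion tensor fit (log-linear)
#'
#' Linear least-squares fit of `log S = log S0 - b g' D g` to the b=0 plus
#' one-shell volumes.  Signals are clipped to `eps` times the per-voxel mean
#' b=0 signal before the log (negative or zero values are possible in
#' real-rotated data; the clip count is an important diagnostic there).
#' Eigenvalues are clipped at zero for FA/MD.  Residuals are kept in signal
#' space for the resolution module.
#'
#' @param ds a `dwi_dataset`.
#' @param shell_b shell to fit (plus all b=0 volumes); default 1000.
#' @param mask optional 3-D logical mask (default: whole volume).
#' @param method `"ols"` (default, log-domain ordinary least squares) or
#'   `"wls"` (one reweighted pass with squared-signal weights).
#' @param eps relative clip level for the log transform.
#' @return object of class `tensor_fit`: 3-D maps `fa`, `md`, `s0`,
#'   eigenvalue array, `v1` (x,y,z,3), per-voxel tensor elements,
#'   signal-space `residuals` over the used `volumes`, and `clip_count`.
#' @export
fit_dti <- function(ds, shell_b = 1000, mask = NULL,
                    method = c("ols", "wls"), eps = 1e-6) {
  stopifnot(inherits(ds, "dwi_dataset"))
  method <- match.arg(method)
  d <- dim(ds$data)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  b0 <- b0_indices(ds$grad)
  idx <- sort(c(b0, shell_indices(ds, shell_b)))
  if (length(idx) < 7L)
    stop(sprintf("only %d usable volumes; need >= 7", length(idx)))
  X <- dti_design(ds$grad$bvals[idx], ds$grad$bvecs[idx, , drop = FALSE])
  nvol <- length(idx)
  nv <- prod(d[1:3])
  Y <- matrix(ds$data[, , , idx], nv, nvol)
  if (is.complex(Y)) Y <- Mod(Y)
  mv <- as.vector(mask)
  Y <- Y[mv, , drop = FALSE]
  b0m <- rowMeans(Y[, match(b0, idx), drop = FALSE])
  floorv <- eps * pmax(b0m, .Machine$double.eps)
  nclip <- sum(sweep(Y, 1, floorv, `<`))
  Yc <- pmax(Y, floorv)
  L <- log(Yc)
  beta <- solve(crossprod(X), crossprod(X, t(L)))   # 7 x nvox
  if (method == "wls") {
    # one reweighted pass, weights = squared predicted signal
    W2 <- exp(2 * t(X %*% beta))                    # nvox x nvol
    for (i in seq_len(nrow(L))) {
      w <- W2[i, ]
      Xw <- X * w
      beta[, i] <- solve(crossprod(Xw, X), crossprod(Xw, L[i, ]))
    }
  }
  e3 <- .eig3_batch_cpp(t(beta[2:7, , drop = FALSE]))
  ev <- pmax(e3$evals, 0)
  fa <- fa_from_eigenvalues(ev)
  md <- rowMeans(ev)
  pred <- exp(t(X %*% beta))                        # nvox x nvol
  resid <- Y - pred

  fill3 <- function(v) { a <- array(NA_real_, d[1:3]); a[mv] <- v; a }
  fill4 <- function(m, n4) {
    a <- array(0, c(d[1:3], n4))
    flat <- matrix(0, nv, n4); flat[mv, ] <- m
    a[] <- flat
    a
  }
  structure(list(fa = fill3(fa), md = fill3(md),
                 s0 = fill3(exp(beta[1, ])),
                 eigenvalues = fill4(ev, 3), v1 = fill4(e3$v1, 3),
                 d_elements = fill4(t(beta[2:7, , drop = FALSE]), 6),
                 residuals = fill4(resid, nvol),
                 prediction = fill4(pred, nvol),
                 volumes = idx, mask = mask, method = method,
                 clip_count = nclip, design = X),
            class = "tensor_fit")
}

#' Model prediction of a tensor fit
#' @param fit a `tensor_fit`.
#' @return 4-D predicted signal over `fit$volumes` (zero outside the mask).
#' @export
predict_dti <- function(fit) {
  stopifnot(inherits(fit, "tensor_fit"))
  fit$prediction
}

dki_design <- function(bvals, bvecs) {
  g <- bvecs; b <- bvals
  # 15 distinct quartic monomials with multinomial multiplicities
  q <- cbind(g[, 1]^4, g[, 2]^4, g[, 3]^4,
             4 * g[, 1]^3 * g[, 2], 4 * g[, 1]^3 * g[, 3],
             4 * g[, 2]^3 * g[, 1], 4 * g[, 2]^3 * g[, 3],
             4 * g[, 3]^3 * g[, 1], 4 * g[, 3]^3 * g[, 2],
             6 * g[, 1]^2 * g[, 2]^2, 6 * g[, 1]^2 * g[, 3]^2,
             6 * g[, 2]^2 * g[, 3]^2,
             12 * g[, 1]^2 * g[, 2] * g[, 3],
             12 * g[, 2]^2 * g[, 1] * g[, 3],
             12 * g[, 3]^2 * g[, 1] * g[, 2])
  cbind(dti_design(b, g), (b^2 / 6) * q)
}

#' Diffusion kurtosis fit (log-linear, two shells)
#'
#' Linear least squares of the quadratic-in-b kurtosis expansion (6 tensor +
#' 15 quartic coefficients + log S0) on two nonzero shells plus b=0.  Data
#' generated by a pure tensor recover the tensor with kurtosis terms ~ 0.
#' Used chiefly to supply residuals for the resolution module.
#'
#' @param ds a `dwi_dataset`.
#' @param shells two nonzero shell b-values (default c(1000, 2000)).
#' @param mask optional 3-D logical mask.
#' @param eps relative clip level for the log transform.
#' @return list with `coeffs` (22 x nvox), `residuals` and `prediction`
#'   (4-D over `volumes`), `volumes`, `mask`, `clip_count`.
#' @export
fit_dki <- function(ds, shells = c(1000, 2000), mask = NULL, eps = 1e-6) {
  stopifnot(inherits(ds, "dwi_dataset"), length(shells) == 2L)
  d <- dim(ds$data)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  b0 <- b0_indices(ds$grad)
  idx <- sort(c(b0, shell_indices(ds, shells[1]), shell_indices(ds, shells[2])))
  X <- dki_design(ds$grad$bvals[idx], ds$grad$bvecs[idx, , drop = FALSE])
  if (length(idx) < ncol(X) + 1L)
    stop("not enough volumes for the 22-parameter kurtosis fit")
  nv <- prod(d[1:3]); nvol <- length(idx)
  Y <- matrix(ds$data[, , , idx], nv, nvol)
  if (is.complex(Y)) Y <- Mod(Y)
  mv <- as.vector(mask)
  Y <- Y[mv, , drop = FALSE]
  b0m <- rowMeans(Y[, match(b0, idx), drop = FALSE])
  floorv <- eps * pmax(b0m, .Machine$double.eps)
  nclip <- sum(sweep(Y, 1, floorv, `<`))
  L <- log(pmax(Y, floorv))
  beta <- solve(crossprod(X), crossprod(X, t(L)))
  pred <- exp(t(X %*% beta))
  resid <- Y - pred
  fill4 <- function(m, n4) {
    a <- array(0, c(d[1:3], n4))
    flat <- matrix(0, nv, n4); flat[mv, ] <- m
    a[] <- flat
    a
  }
  list(coeffs = beta, residuals = fill4(resid, nvol),
       prediction = fill4(pred, nvol), volumes = idx, mask = mask,
       clip_count = nclip)
}

#' Wild-bootstrap uncertainty of DTI parameters
#'
#' Residual resampling in the log domain: each replicate refits
#' `y* = yhat + r_adj .* h` with i.i.d. Rademacher signs `h` per data point
#' and HC2 leverage rescaling `r_adj = r / sqrt(1 - h_ii)`, preserving
#' heteroscedasticity.  Uncertainty is the per-voxel standard deviation of
#' FA and MD across the replicates.
#'
#' @param ds a `dwi_dataset`.
#' @param shell_b shell to fit; default 1000.
#' @param mask optional 3-D logical mask.
#' @param n number of bootstrap replicates (default 250).
#' @param seed integer seed.
#' @param leverage `"hc2"` (default) or `"none"` (plain Rademacher).
#' @return object of class `bootstrap_result` with `fa_sd`, `md_sd` (3-D),
#'   `n_samples`, `seed`.
#' @export
wild_bootstrap <- function(ds, shell_b = 1000, mask = NULL, n = 250L,
                           seed = 1L, leverage = c("hc2", "none")) {
  leverage <- match.arg(leverage)
  fit <- fit_dti(ds, shell_b = shell_b, mask = mask, method = "ols")
  d <- dim(ds$data)
  mask <- fit$mask
  mv <- as.vector(mask)
  idx <- fit$volumes
  X <- fit$design
  nvol <- length(idx)
  nvox <- sum(mv)
  Y <- matrix(ds$data[, , , idx], prod(d[1:3]), nvol)[mv, , drop = FALSE]
  if (is.complex(Y)) Y <- Mod(Y)
  b0m <- rowMeans(Y[, ds$grad$bvals[idx] <= ds$grad$b0_threshold,
                    drop = FALSE])
  L <- t(log(pmax(Y, 1e-6 * pmax(b0m, .Machine$double.eps)))) # nvol x nvox
  XtXi <- solve(crossprod(X))
  P <- XtXi %*% t(X)
  hii <- rowSums((X %*% XtXi) * X)
  beta <- P %*% L
  Lhat <- X %*% beta
  R <- L - Lhat
  if (leverage == "hc2") R <- R / sqrt(pmax(1 - hii, .Machine$double.eps))

  set.seed(seed)
  fa_acc <- matrix(0, nvox, 2)  # running sum, sum of squares
  md_acc <- matrix(0, nvox, 2)
  for (r in seq_len(n)) {
    H <- matrix(sample(c(-1, 1), nvol * nvox, replace = TRUE), nvol, nvox)
    bstar <- P %*% (Lhat + R * H)
    e3 <- .eig3_batch_cpp(t(bstar[2:7, , drop = FALSE]))
    ev <- pmax(e3$evals, 0)
    fa <- fa_from_eigenvalues(ev)
    md <- rowMeans(ev)
    fa_acc[, 1] <- fa_acc[, 1] + fa; fa_acc[, 2] <- fa_acc[, 2] + fa^2
    md_acc[, 1] <- md_acc[, 1] + md; md_acc[, 2] <- md_acc[, 2] + md^2
  }
  sd_of <- function(acc) sqrt(pmax(acc[, 2] / n - (acc[, 1] / n)^2, 0) *
                              n / (n - 1))
  fill3 <- function(v) { a <- array(NA_real_, d[1:3]); a[mv] <- v; a }
  structure(list(fa_sd = fill3(sd_of(fa_acc)), md_sd = fill3(sd_of(md_acc)),
                 n_samples = n, seed = seed),
            class = "bootstrap_result")
}

#' Agreement of a scalar map with a reference
#'
#' Pearson correlation and sum of squared differences over the mask.
#'
#' @param map,ref_map 3-D scalar maps of matching geometry.
#' @param mask non-empty 3-D logical mask.
#' @return list with `pearson_r` and `sse`.
#' @export
accuracy_vs_reference <- function(map, ref_map, mask) {
  stopifnot(all(dim(map) == dim(ref_map)), any(mask))
  a <- map[mask]; b <- ref_map[mask]
  ok <- is.finite(a) & is.finite(b)
  list(pearson_r = cor(a[ok], b[ok]), sse = sum((a[ok] - b[ok])^2))
}

#' Angularly uniform subset of directions
#'
#' Greedy maximin selection on the sphere (antipodally symmetric distance
#' `acos(|g_i . g_j|)`): a seeded random first pick, then each new direction
#' maximises its minimum angle to those already kept.  Keeps subsets
#' near-uniform, avoiding the conditioning artefacts of random subsampling.
#'
#' @param bvecs n x 3 unit direction matrix.
#' @param m number of directions to keep.
#' @param seed integer seed for the first pick.
#' @return integer vector of m row indices.
#' @export
subset_directions <- function(bvecs, m, seed = 1L) {
  n <- nrow(bvecs)
  stopifnot(m >= 1, m <= n)
  set.seed(seed)
  first <- sample.int(n, 1)
  kept <- first
  cosang <- abs(bvecs %*% t(bvecs))
  cosang[cosang > 1] <- 1
  dist <- acos(cosang)                      # angular distance, antipodal-aware
  mind <- dist[, first]
  while (length(kept) < m) {
    cand <- which.max(replace(mind, kept, -Inf))
    kept <- c(kept, cand)
    mind <- pmin(mind, dist[, cand])
  }
  sort(kept)
}

#' Convergence of DTI maps with the fraction of directions kept
#'
#' For each fraction: subsample every diffusion-weighted shell to that
#' fraction of its directions (greedy uniform selection, seeded), optionally
#' denoise the subset, fit the tensor to `shell_b`, and score FA and MD
#' against reference maps.
#'
#' @param ds a `dwi_dataset`.
#' @param fractions numeric vector in (0, 1].
#' @param reference_maps list with 3-D `fa` and `md` reference maps.
#' @param mask 3-D logical scoring mask.
#' @param seed integer seed for subset selection.
#' @param shell_b shell for the tensor fit.
#' @param denoiser optional function `dwi_dataset -> dwi_dataset` applied to
#'   each subset before fitting.
#' @return data.frame: fraction, n_volumes, fa_r, fa_sse, md_r, md_sse.
#' @export
subset_convergence <- function(ds, fractions, reference_maps, mask,
                               seed = 1L, shell_b = 1000, denoiser = NULL) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  sh <- shell_split(ds)
  b0 <- b0_indices(ds$grad)
  rows <- lapply(fractions, function(f) {
    keep <- b0
    for (lab in names(sh)) {
      if (as.numeric(lab) <= ds$grad$b0_threshold) next
      idx <- sh[[lab]]
      m <- max(6L, round(f * length(idx)))
      pick <- subset_directions(ds$grad$bvecs[idx, , drop = FALSE],
                                min(m, length(idx)), seed = seed)
      keep <- c(keep, idx[pick])
    }
    sub <- subset_volumes(ds, sort(keep))
    if (!is.null(denoiser)) sub <- denoiser(sub)
    fit <- fit_dti(sub, shell_b = shell_b, mask = mask)
    fa_s <- accuracy_vs_reference(fit$fa, reference_maps$fa, mask)
    md_s <- accuracy_vs_reference(fit$md, reference_maps$md, mask)
    data.frame(fraction = f, n_volumes = length(keep),
               fa_r = fa_s$pearson_r, fa_sse = fa_s$sse,
               md_r = md_s$pearson_r, md_sse = md_s$sse)
  })
  do.call(rbind, rows)
}
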