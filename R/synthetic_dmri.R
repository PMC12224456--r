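#' Phantom specification
#'
#' Describes a synthetic multi-shell diffusion phantom.  Defaults emulate a
#' desk-scale version of a UK-Biobank-like two-shell protocol: b = 1000 and
#' 2000 s/mm^2 shells plus interleaved b=0 volumes, at one of three SNR
#' regimes (around 30, 15 or 5 at b=0 in the reference tissue).
#'
#' @param grid_shape 3 positive integers, image matrix size.
#' @param voxel_size voxel edge lengths (mm).
#' @param shells list of `c(b_value, n_directions)` pairs.
#' @param n_b0 number of b = 0 s/mm^2 volumes (placed first).
#' @param snr_b0 target SNR at b = 0 in the single-fibre reference tissue.
#' @param sigma_map_model `"uniform"` or `"radial_gradient"`; the radial model
#'   doubles sigma at the grid centre relative to the edge, emulating
#'   spatially varying noise after multi-coil reconstruction.
#' @param phase_model `"zero"`, `"smooth_polynomial"` (per-slice second-order
#'   polynomial) or `"smooth_plus_jitter"` (adds high-spatial-frequency
#'   noise on top of the smooth field).
#' @param tissue_model orientation structure of the generic tissue
#'   compartment: `"smooth_rotation"` (fibre orientation rotates smoothly,
#'   90 degrees per 24 voxels -- low-rank over any patch) or
#'   `"fibre_domains"` (independent random orientation per 4-voxel block,
#'   emulating fascicle domains: patches much larger than a domain mix many
#'   distinct angular signatures, which is what degrades patch-PCA at large
#'   patch sizes).
#' @param seed integer; the phantom is bit-reproducible given the seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(24, 24, 12),
                         voxel_size = c(2, 2, 2),
                         shells = list(c(1000, 32), c(2000, 32)),
                         n_b0 = 6,
                         snr_b0 = 30,
                         sigma_map_model = c("uniform", "radial_gradient"),
                         phase_model = c("smooth_polynomial", "zero",
                                         "smooth_plus_jitter"),
                         tissue_model = c("smooth_rotation", "fibre_domains"),
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1),
            snr_b0 > 0, length(shells) >= 1L, n_b0 >= 1)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size),
                 shells = shells, n_b0 = as.integer(n_b0),
                 snr_b0 = snr_b0,
                 sigma_map_model = match.arg(sigma_map_model),
                 phase_model = match.arg(phase_model),
                 tissue_model = match.arg(tissue_model),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Near-uniform diffusion directions by electrostatic repulsion
#'
#' Starts from a seeded random set on the sphere and relaxes it with
#' antipodally symmetric electrostatic repulsion, giving near-uniform
#' angular coverage suitable for spherical-harmonic fitting.
#'
#' @param n number of directions.
#' @param seed integer seed; the result is deterministic given the seed.
#' @param n_iter relaxation iterations.
#' @return n x 3 matrix of unit vectors.
#' @export
uniform_directions <- function(n, seed = 1L, n_iter = 150L) {
  set.seed(seed)
  x <- matrix(rnorm(3 * n), n, 3)
  x <- x / sqrt(rowSums(x^2))
  if (n == 1L) return(x)
  step <- 0.05
  for (it in seq_len(n_iter)) {
    f <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      d1 <- sweep(-x, 2, -x[i, ])            # x_i - x_j
      d2 <- sweep(x, 2, x[i, ], "+")         # x_i + x_j
      r1 <- pmax(sqrt(rowSums(d1^2)), 1e-6)
      r2 <- pmax(sqrt(rowSums(d2^2)), 1e-6)
      r1[i] <- Inf
      f[i, ] <- colSums(d1 / r1^3) + colSums(d2 / r2^3)
    }
    x <- x + step * f / max(sqrt(rowSums(f^2)))
    x <- x / sqrt(rowSums(x^2))
    step <- step * 0.985
  }
  x
}

tensor6 <- function(evals, v1) {
  # symmetric tensor from eigenvalues (desc) and principal axis; the two
  # minor axes are any orthonormal completion (isotropic in the minor plane
  # when evals[2] == evals[3])
  v1 <- v1 / sqrt(sum(v1^2))
  a <- if (abs(v1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v2 <- a - sum(a * v1) * v1
  v2 <- v2 / sqrt(sum(v2^2))
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  D <- evals[1] * tcrossprod(v1) + evals[2] * tcrossprod(v2) +
       evals[3] * tcrossprod(v3)
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

#' Fractional anisotropy from eigenvalues
#' @param evals numeric length-3 (or n x 3 matrix) of tensor eigenvalues.
#' @return FA in [0, 1].
#' @export
fa_from_eigenvalues <- function(evals) {
  if (is.null(dim(evals))) evals <- matrix(evals, 1)
  mb <- rowMeans(evals)
  num <- rowSums((evals - mb)^2)
  den <- rowSums(evals^2)
  fa <- sqrt(1.5 * num / pmax(den, .Machine$double.eps))
  fa[den == 0] <- 0
  if (length(fa) == 1L) fa[[1]] else fa
}

#' Build a phantom with known ground truth
#'
#' Lays out four labelled compartments on the grid -- a CSF-like isotropic
#' high-diffusivity sphere (MD = 3.0e-3 mm^2/s), a coherent single-fibre
#' block (eigenvalues (1.7, 0.2, 0.2)e-3 mm^2/s, FA ~ 0.87), a two-tensor
#' 90-degree crossing block, and zero-signal background -- embedded in
#' anisotropic tissue whose fibre orientation rotates smoothly across the
#' volume (emulating orientation variation across the brain, which makes
#' large denoising patches genuinely heterogeneous).  Also draws the gradient
#' table, the true noise sigma map and smooth per-slice phase fields.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_gt` with fields `clean_signal` (4-D
#'   noiseless signal), `s0_map`, `sigma_map`, `phase_field` (4-D, radians),
#'   `rois` (named logical masks), `grad` (the gradient table), `fractions`
#'   and `tensors` (per-voxel mixture), and `voxel_size`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]; nz <- spec$grid_shape[3]
  if (min(nx, ny) < 12 || nz < 6)
    stop("grid too small to place all ROIs (need at least 12 x 12 x 6)")
  set.seed(spec$seed)
  nvox <- nx * ny * nz

  ix <- rep(seq_len(nx), times = ny * nz)
  iy <- rep(rep(seq_len(ny), each = nx), times = nz)
  iz <- rep(seq_len(nz), each = nx * ny)

  margin <- 2L
  object <- ix > margin & ix <= nx - margin &
            iy > margin & iy <= ny - margin &
            iz > 1L & iz <= nz - 1L

  # CSF-like ventricle analogue: ellipsoid, plus an interior core whose
  # voxels sit well away from the tissue boundary (floor statistics should
  # not be contaminated by partial-window effects of patch/window methods)
  csf_c <- c(0.32 * nx, 0.32 * ny, (nz + 1) / 2)
  csf_r <- max(2, round(min(nx, ny) / 5))
  csf_rz <- max(2, min(csf_r, floor(nz / 2) - 2))
  edist <- function(r, rz) ((ix - csf_c[1])^2 + (iy - csf_c[2])^2) / r^2 +
    (iz - csf_c[3])^2 / rz^2
  csf <- object & edist(csf_r, csf_rz) <= 1
  # 4-voxel margin: a 3-voxel search window plus 1-voxel patch never leaves
  # the CSF compartment from a core voxel
  csf_core <- object & edist(max(csf_r - 4, 1), max(csf_rz - 4, 1)) <= 1

  inbox <- function(fx, fy) {
    ix >= ceiling(fx[1] * nx) & ix <= floor(fx[2] * nx) &
    iy >= ceiling(fy[1] * ny) & iy <= floor(fy[2] * ny) &
    iz >= max(2L, ceiling(0.25 * nz)) & iz <= min(nz - 1L, floor(0.8 * nz))
  }
  fibre <- object & !csf & inbox(c(0.55, 0.85), c(0.15, 0.45))
  crossing <- object & !csf & !fibre & inbox(c(0.55, 0.85), c(0.55, 0.85))
  background <- !object
  tissue <- object & !csf & !fibre & !crossing
  if (!any(csf) || !any(fibre) || !any(crossing))
    stop("grid too small to place all ROIs")

  to3d <- function(v) array(v, c(nx, ny, nz))

  # per-voxel two-population mixture
  f1 <- rep(1, nvox); f2 <- rep(0, nvox)
  D1 <- matrix(0, nvox, 6); D2 <- matrix(0, nvox, 6)
  ev_csf <- c(3e-3, 3e-3, 3e-3)
  ev_wm <- c(1.7e-3, 0.2e-3, 0.2e-3)
  ev_tis <- c(1.2e-3, 0.4e-3, 0.4e-3)

  D1[csf, ] <- matrix(tensor6(ev_csf, c(1, 0, 0)), sum(csf), 6, byrow = TRUE)
  D1[fibre, ] <- matrix(tensor6(ev_wm, c(1, 0, 0)), sum(fibre), 6, byrow = TRUE)
  D1[crossing, ] <- matrix(tensor6(ev_wm, c(1, 0, 0)), sum(crossing), 6,
                           byrow = TRUE)
  D2[crossing, ] <- matrix(tensor6(ev_wm, c(0, 1, 0)), sum(crossing), 6,
                           byrow = TRUE)
  f1[crossing] <- 0.5; f2[crossing] <- 0.5

  # tissue: orientation rotates with x (90 degrees across the grid), so
  # large patches are genuinely heterogeneous, and overall diffusivity
  # drifts smoothly with y (+-20%), so mean diffusivity has real spatial
  # contrast (a constant-MD compartment would make MD correlations against
  # ground truth degenerate)
  # orientation coherence length is a fixed number of voxels, not a fraction
  # of the field of view: patch heterogeneity is a property of the tissue,
  # and must not vanish on larger grids
  tt <- which(tissue)
  mdscale <- 0.8 + 0.4 * (iy[tt] - 1) / max(ny - 1, 1)
  if (spec$tissue_model == "smooth_rotation") {
    theta <- (pi / 2) * (ix[tt] - 1) / 24
    for (k in seq_along(tt)) {
      D1[tt[k], ] <- tensor6(mdscale[k] * ev_tis,
                             c(cos(theta[k]), sin(theta[k]), 0))
    }
  } else {                                  # fibre_domains
    dom <- 4L
    bx <- (ix[tt] - 1) %/% dom; by <- (iy[tt] - 1) %/% dom
    bz <- (iz[tt] - 1) %/% dom
    bid <- bx + 1000L * (by + 1000L * bz)
    ub <- unique(bid)
    ori <- matrix(rnorm(3 * length(ub)), length(ub), 3)
    ori <- ori / sqrt(rowSums(ori^2))
    rownames(ori) <- as.character(ub)
    for (k in seq_along(tt)) {
      D1[tt[k], ] <- tensor6(mdscale[k] * ev_tis,
                             ori[as.character(bid[k]), ])
    }
  }
  D1[background, ] <- matrix(tensor6(c(1e-3, 1e-3, 1e-3), c(1, 0, 0)),
                             sum(background), 6, byrow = TRUE)

  s0 <- rep(0, nvox)
  s0[object] <- 1

  sigma_ref <- 1 / spec$snr_b0
  if (spec$sigma_map_model == "uniform") {
    sigma <- rep(sigma_ref, nvox)
  } else {
    r <- sqrt(((ix - (nx + 1) / 2) / (nx / 2))^2 +
              ((iy - (ny + 1) / 2) / (ny / 2))^2 +
              ((iz - (nz + 1) / 2) / (nz / 2))^2)
    g <- 2 - pmin(r, 1)                     # 2x sigma at centre vs edge
    sigma <- sigma_ref * g / mean(g[fibre]) # reference tissue keeps snr_b0
  }

  # gradient table: b0 volumes first, then each shell
  bvals <- rep(0, spec$n_b0)
  bvecs <- matrix(0, spec$n_b0, 3)
  for (si in seq_along(spec$shells)) {
    sh <- spec$shells[[si]]
    dirs <- uniform_directions(sh[2], seed = spec$seed + si)
    bvals <- c(bvals, rep(sh[1], sh[2]))
    bvecs <- rbind(bvecs, dirs)
  }
  grad <- gradient_table(bvals, bvecs)
  nvol <- length(bvals)

  # smooth per-slice, per-volume phase fields (the smooth component is kept
  # separately so the low-pass estimator can be scored against it).  The
  # jitter variant adds phase confined to high spatial frequencies (k-space
  # radius > 0.9 Nyquist), far enough above the low-pass estimator's cutoff
  # that even modulation sidebands (from the smooth field and the object
  # boundary) stay outside the pass band.
  phase <- array(0, c(nx, ny, nz, nvol))
  phase_smooth <- phase
  if (spec$phase_model != "zero") {
    u <- (ix[1:(nx * ny)] - (nx + 1) / 2) / (nx / 2)
    w <- (iy[1:(nx * ny)] - (ny + 1) / 2) / (ny / 2)
    if (spec$phase_model == "smooth_plus_jitter") {
      fr <- function(n) {
        k <- 0:(n - 1)
        ifelse(k > n / 2, k - n, k) / (n / 2)
      }
      hp <- sqrt(outer(fr(nx)^2, fr(ny)^2, `+`)) > 0.9
    }
    for (v in seq_len(nvol)) for (z in seq_len(nz)) {
      a <- rnorm(6, 0, 0.35)
      ph <- a[1] + a[2] * u + a[3] * w + a[4] * u^2 + a[5] * u * w + a[6] * w^2
      phase_smooth[, , z, v] <- ph
      if (spec$phase_model == "smooth_plus_jitter") {
        jit <- Re(fft(fft(matrix(rnorm(nx * ny), nx, ny)) * hp,
                      inverse = TRUE)) / (nx * ny)
        jit <- jit / sd(jit) * 0.08
        ph <- ph + as.vector(jit)
      }
      phase[, , z, v] <- ph
    }
  }

  gt <- structure(list(
    grid_shape = spec$grid_shape,
    voxel_size = spec$voxel_size,
    fractions = cbind(f1, f2),
    tensors = list(D1 = D1, D2 = D2),
    s0_map = to3d(s0),
    sigma_map = to3d(sigma),
    phase_field = phase,
    phase_smooth = phase_smooth,
    rois = list(csf_like = to3d(csf), csf_core = to3d(csf_core),
                single_fibre = to3d(fibre),
                crossing = to3d(crossing), background = to3d(background),
                tissue = to3d(tissue), object = to3d(object)),
    grad = grad,
    spec = spec), class = "phantom_gt")
  gt$clean_signal <- simulate_signal(gt, grad)
  gt
}

#' Noiseless multi-tensor signal
#'
#' Evaluates the multi-tensor attenuation
#' `S(b, g) = S0 * sum_k f_k exp(-b g' D_k g)` for every voxel and volume;
#' b = 0 volumes equal the S0 map exactly.
#'
#' @param gt a `phantom_gt` (tensors, fractions, S0 map).
#' @param grad a [gradient_table()].
#' @return 4-D noiseless signal array.
#' @export
simulate_signal <- function(gt, grad) {
  stopifnot(inherits(gt, "phantom_gt"), inherits(grad, "gradient_table"))
  dims <- gt$grid_shape
  nvox <- prod(dims)
  nvol <- length(grad$bvals)
  s0 <- as.vector(gt$s0_map)
  f <- gt$fractions
  D1 <- gt$tensors$D1; D2 <- gt$tensors$D2
  out <- matrix(0, nvox, nvol)
  for (j in seq_len(nvol)) {
    b <- grad$bvals[j]
    if (b == 0) { out[, j] <- s0; next }
    g <- grad$bvecs[j, ]
    q <- c(g[1]^2, g[2]^2, g[3]^2, 2 * g[1] * g[2], 2 * g[1] * g[3],
           2 * g[2] * g[3])
    a1 <- exp(-b * as.vector(D1 %*% q))
    sig <- f[, 1] * a1
    has2 <- f[, 2] > 0
    if (any(has2)) {
      a2 <- exp(-b * as.vector(D2[has2, , drop = FALSE] %*% q))
      sig[has2] <- sig[has2] + f[has2, 2] * a2
    }
    out[, j] <- s0 * sig
  }
  array(out, c(dims, nvol))
}

#' Corrupt a clean signal with complex Gaussian noise and a phase field
#'
#' Forms `clean * exp(1i * phase) + (eps_r + 1i * eps_i)` with independent
#' zero-mean Gaussian channels whose per-voxel standard deviation comes from
#' the phantom's sigma map (the single-effective-channel model of
#' SENSE1-style reconstructions; the magnitude is then Rician).
#'
#' @param clean 4-D noiseless signal.
#' @param gt a `phantom_gt` providing `sigma_map` and `phase_field`.
#' @param seed integer; identical seeds give identical noise.
#' @return a complex-domain `dwi_dataset` with the true sigma map attached.
#' @export
add_complex_noise <- function(clean, gt, seed = 1L) {
  stopifnot(inherits(gt, "phantom_gt"))
  d <- dim(clean)
  stopifnot(length(d) == 4L, all(dim(gt$phase_field) == d))
  set.seed(seed)
  sdv <- rep(as.vector(gt$sigma_map), times = d[4])
  n <- length(clean)
  noisy <- as.vector(clean) * exp(1i * as.vector(gt$phase_field)) +
    complex(real = rnorm(n, 0, sdv), imaginary = rnorm(n, 0, sdv))
  dim(noisy) <- d
  dwi_dataset(noisy, gt$grad, gt$voxel_size, "complex", gt$sigma_map)
}

#' Independent noisy repeats of one phantom
#'
#' All repeats share the clean signal and phase fields exactly; only the
#' thermal noise differs (repeats are perfectly aligned -- no motion).
#'
#' @param gt a `phantom_gt`.
#' @param grad gradient table (defaults to the phantom's own).
#' @param n_repeats number of repeats.
#' @param seed integer; repeat r uses `seed + r - 1`.
#' @return list of complex-domain `dwi_dataset`s.
#' @export
make_repeats <- function(gt, grad = gt$grad, n_repeats = 1L, seed = 1L) {
  stopifnot(n_repeats >= 1)
  clean <- if (identical(grad, gt$grad)) gt$clean_signal
           else simulate_signal(gt, grad)
  lapply(seq_len(n_repeats), function(r)
    add_complex_noise(clean, gt, seed = seed + r - 1L))
}
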