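#' Gradient table
#'
#' Holds the diffusion-weighting strength (b-value, s/mm^2) and sensitising
#' direction (unit b-vector, image coordinate frame) of every volume in a
#' 4-D acquisition.  Directions of diffusion-weighted volumes are
#' renormalised to unit length on construction; b=0 volumes may carry a zero
#' vector (their direction is undefined).
#'
#' @param bvals numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs matrix of b-vectors: either n x 3 (rows = volumes) or 3 x n
#'   (FSL file layout); coerced to n x 3.
#' @param b0_threshold b-value (s/mm^2) at or below which a volume is treated
#'   as b = 0. Default 50 separates nominal b=0 volumes from the weakest
#'   diffusion-weighted shells of standard multi-shell protocols.
#' @return object of class `gradient_table`.
#' @export
gradient_table <- function(bvals, bvecs, b0_threshold = 50) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) == 3L && ncol(bvecs) != 3L) bvecs <- t(bvecs)
  if (ncol(bvecs) != 3L)
    stop("bvecs must have 3 components per direction")
  storage.mode(bvecs) <- "double"
  dimnames(bvecs) <- NULL
  if (length(bvals) != nrow(bvecs))
    stop(sprintf("gradient table mismatch: %d b-values but %d b-vectors",
                 length(bvals), nrow(bvecs)))
  if (any(bvals < 0)) stop("b-values must be non-negative")
  nrm <- sqrt(rowSums(bvecs^2))
  dw <- bvals > b0_threshold
  if (any(dw & nrm < 1e-8))
    stop("diffusion-weighted volume has a zero b-vector")
  bvecs[dw, ] <- bvecs[dw, , drop = FALSE] / nrm[dw]
  structure(list(bvals = bvals, bvecs = bvecs, b0_threshold = b0_threshold),
            class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  sh <- table(round(x$bvals, -1))
  cat(sprintf("<gradient_table> %d volumes; b-values: %s\n",
              length(x$bvals),
              paste(sprintf("%s (n=%d)", names(sh), as.integer(sh)),
                    collapse = ", ")))
  invisible(x)
}

#' Number of volumes in a gradient table or dataset
#' @param x a `gradient_table` or `dwi_dataset`.
#' @return integer count of volumes.
#' @export
n_volumes <- function(x) {
  if (inherits(x, "dwi_dataset")) length(x$grad$bvals) else length(x$bvals)
}

#' Indices of b=0 volumes
#' @param grad a `gradient_table`.
#' @return integer vector of volume indices (1-based).
#' @export
b0_indices <- function(grad) which(grad$bvals <= grad$b0_threshold)

#' Indices of diffusion-weighted volumes
#' @param grad a `gradient_table`.
#' @return integer vector of volume indices (1-based).
#' @export
dw_indices <- function(grad) which(grad$bvals > grad$b0_threshold)

#' 4-D diffusion MRI dataset
#'
#' Couples a 4-D voxel array (x, y, z, volume) with its gradient table,
#' voxel geometry, signal domain, and an optional noise sigma map.
#'
#' @param data 4-D numeric or complex array, dimensions (x, y, z, volume).
#' @param grad a [gradient_table()]; its length must match the 4th dimension.
#' @param voxel_size length-3 positive numeric, voxel edge lengths in mm.
#' @param domain one of `"magnitude"`, `"complex"`, `"real_rotated"`.
#' @param sigma_map optional 3-D noise sigma map in signal units.
#' @return object of class `dwi_dataset`.
#' @export
dwi_dataset <- function(data, grad,
                        voxel_size = c(2, 2, 2),
                        domain = c("magnitude", "complex", "real_rotated"),
                        sigma_map = NULL) {
  domain <- match.arg(domain)
  stopifnot(inherits(grad, "gradient_table"))
  d <- dim(data)
  if (length(d) != 4L)
    stop("data must be a 4-D array (x, y, z, volume)")
  if (d[4] != length(grad$bvals))
    stop(sprintf("dimension mismatch: image has %d volumes, gradient table has %d entries",
                 d[4], length(grad$bvals)))
  if (domain == "complex") {
    if (!is.complex(data)) data <- data + 0i
  } else {
    if (is.complex(data)) stop("complex data require domain = 'complex'")
    if (domain == "magnitude" && any(data < 0))
      stop("magnitude-domain data must be non-negative")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be 3 strictly positive lengths (mm)")
  if (!is.null(sigma_map)) {
    stopifnot(all(dim(sigma_map) == d[1:3]))
    if (any(sigma_map < 0)) stop("sigma_map must be non-negative")
  }
  structure(list(data = data, grad = grad, voxel_size = voxel_size,
                 domain = domain, sigma_map = sigma_map),
            class = "dwi_dataset")
}

#' @export
print.dwi_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dwi_dataset> %dx%dx%d voxels, %d volumes, %s domain, voxels %s mm\n",
              d[1], d[2], d[3], d[4], x$domain,
              paste(signif(x$voxel_size, 3), collapse = "x")))
  invisible(x)
}

#' Magnitude view of a dataset
#'
#' Takes the voxelwise modulus, turning complex or real-rotated data into a
#' magnitude-domain dataset.
#'
#' @param ds a `dwi_dataset`.
#' @return a `dwi_dataset` with `domain = "magnitude"`.
#' @export
as_magnitude <- function(ds) {
  stopifnot(inherits(ds, "dwi_dataset"))
  mag <- Mod(ds$data)
  dim(mag) <- dim(ds$data)
  dwi_dataset(mag, ds$grad, ds$voxel_size, "magnitude", ds$sigma_map)
}

#' Read FSL-style gradient files
#'
#' @param bval_path,bvec_path whitespace-separated text files; bvals on one
#'   line, bvecs as three rows (x, y, z) of direction components.
#' @param b0_threshold passed to [gradient_table()].
#' @return a `gradient_table`.
#' @export
read_gradients <- function(bval_path, bvec_path, b0_threshold = 50) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- as.matrix(read.table(bvec_path))
  gradient_table(bvals, bv, b0_threshold)
}

#' Write FSL-style gradient files
#' @param grad a `gradient_table`.
#' @param bval_path,bvec_path output paths.
#' @return invisibly, `grad`.
#' @export
write_gradients <- function(grad, bval_path, bvec_path) {
  writeLines(paste(format(grad$bvals, trim = TRUE), collapse = " "), bval_path)
  bv <- t(grad$bvecs)
  writeLines(apply(bv, 1L, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvec_path)
  invisible(grad)
}

sidecar_path <- function(image_path)
  paste0(sub("\\.nii(\\.gz)?$", "", image_path), ".json")

#' Read a 4-D diffusion dataset from NIfTI + gradient files
#'
#' When `phase_path` is given the returned dataset is complex,
#' `magnitude * exp(1i * phase * phase_scale)`.  The on-disk phase convention
#' (radians vs scaled integers) varies between sites, so a scale factor is
#' accepted rather than guessed.  A JSON sidecar written by [write_dwi()]
#' restores the signal-domain flag.
#'
#' @param image_path 4-D NIfTI-1 image (magnitude or real-valued).
#' @param bval_path,bvec_path FSL-style gradient text files.
#' @param phase_path optional NIfTI phase image of identical dimensions.
#' @param phase_scale multiplier taking stored phase values to radians.
#' @param b0_threshold passed to [gradient_table()].
#' @return a `dwi_dataset`.
#' @export
read_dwi <- function(image_path, bval_path, bvec_path, phase_path = NULL,
                     phase_scale = 1, b0_threshold = 50) {
  img <- RNifti::readNifti(image_path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L)
    stop(sprintf("expected a 4-D image, got %d dimensions", length(dim(arr))))
  grad <- read_gradients(bval_path, bvec_path, b0_threshold)
  if (dim(arr)[4] != length(grad$bvals))
    stop(sprintf("dimension mismatch: image has %d volumes, gradient table has %d entries",
                 dim(arr)[4], length(grad$bvals)))
  vs <- RNifti::pixdim(img)[1:3]
  domain <- "magnitude"
  sc <- sidecar_path(image_path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc)
    # a "complex" sidecar refers to the magnitude+phase pair; without the
    # phase image only the magnitude component is being loaded
    if (!is.null(meta$domain) && meta$domain != "complex")
      domain <- meta$domain
  }
  if (!is.null(phase_path)) {
    ph <- as.array(RNifti::readNifti(phase_path))
    stopifnot(all(dim(ph) == dim(arr)))
    arr <- arr * exp(1i * ph * phase_scale)
    domain <- "complex"
  }
  if (domain == "magnitude" && any(arr < 0)) domain <- "real_rotated"
  dwi_dataset(arr, grad, vs, domain)
}

#' Write a dataset to NIfTI
#'
#' Real-valued data round-trip bit-exactly through a single image; complex
#' data are written as a magnitude image at `image_path` plus a companion
#' `*_phase` image (radians).  A JSON sidecar records the signal domain.
#'
#' @param ds a `dwi_dataset`.
#' @param image_path output NIfTI path (`.nii` or `.nii.gz`).
#' @return invisibly, the paths written.
#' @export
write_dwi <- function(ds, image_path) {
  stopifnot(inherits(ds, "dwi_dataset"))
  if (!dir.exists(dirname(image_path)))
    stop(sprintf("directory does not exist: %s", dirname(image_path)))
  as_img <- function(arr) {
    img <- RNifti::asNifti(arr)
    # pixdim assignment needs one entry per image dimension
    RNifti::pixdim(img) <- c(ds$voxel_size,
                             rep(1, length(dim(arr)) - 3L))
    img
  }
  paths <- image_path
  if (ds$domain == "complex") {
    mag <- Mod(ds$data); dim(mag) <- dim(ds$data)
    ph <- Arg(ds$data); dim(ph) <- dim(ds$data)
    ppath <- sub("(\\.nii(\\.gz)?)$", "_phase\\1", image_path)
    RNifti::writeNifti(as_img(mag), image_path, datatype = "double")
    RNifti::writeNifti(as_img(ph), ppath, datatype = "double")
    paths <- c(image_path, ppath)
  } else {
    RNifti::writeNifti(as_img(ds$data), image_path, datatype = "double")
  }
  jsonlite::write_json(
    list(domain = ds$domain, b0_threshold = ds$grad$b0_threshold,
         voxel_size = ds$voxel_size),
    sidecar_path(image_path), auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Group volumes into b-shells
#'
#' Partitions volume indices by b-value, merging b-values that differ by at
#' most `tolerance` into one shell (labelled with the rounded shell mean).
#' Every volume lands in exactly one shell.
#'
#' @param x a `dwi_dataset` or `gradient_table`.
#' @param tolerance b-values within this distance (s/mm^2) of a shell's first
#'   member are merged into it.
#' @return named list mapping shell b-value to an integer vector of volume
#'   indices (1-based).
#' @export
shell_split <- function(x, tolerance = 50) {
  bvals <- if (inherits(x, "dwi_dataset")) x$grad$bvals else x$bvals
  ord <- order(bvals)
  shells <- list()
  anchor <- NULL
  members <- integer(0)
  flush <- function(shells, members, bvals) {
    lab <- as.character(round(mean(bvals[members])))
    shells[[lab]] <- sort(members)
    shells
  }
  for (i in ord) {
    if (is.null(anchor) || bvals[i] - anchor > tolerance) {
      if (length(members)) shells <- flush(shells, members, bvals)
      anchor <- bvals[i]
      members <- i
    } else {
      members <- c(members, i)
    }
  }
  shells <- flush(shells, members, bvals)
  shells
}

#' Pick the volumes of one shell
#'
#' @param ds a `dwi_dataset`.
#' @param shell_b nominal b-value of the wanted shell.
#' @param tolerance passed to [shell_split()].
#' @return integer vector of volume indices.
#' @export
shell_indices <- function(ds, shell_b, tolerance = 50) {
  sh <- shell_split(ds, tolerance)
  labs <- as.numeric(names(sh))
  j <- which.min(abs(labs - shell_b))
  if (abs(labs[j] - shell_b) > tolerance)
    stop(sprintf("no shell near b = %g (available: %s)", shell_b,
                 paste(names(sh), collapse = ", ")))
  sh[[j]]
}

#' Restrict a dataset to a subset of volumes
#' @param ds a `dwi_dataset`.
#' @param idx integer vector of volume indices to keep.
#' @return a `dwi_dataset` with the selected volumes.
#' @export
subset_volumes <- function(ds, idx) {
  dwi_dataset(ds$data[, , , idx, drop = FALSE],
              gradient_table(ds$grad$bvals[idx],
                             ds$grad$bvecs[idx, , drop = FALSE],
                             ds$grad$b0_threshold),
              ds$voxel_size, ds$domain, ds$sigma_map)
}
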