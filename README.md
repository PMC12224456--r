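# dmridenoise

Patch-based denoising of diffusion MRI in the magnitude and complex
(real-rotated) domains, together with the quantitative framework needed to
judge what a denoiser actually did: variance reduction, noise-floor
suppression, spatial-resolution cost, model-fit precision and accuracy, and
scan-time-reduction potential. Everything is exercised on a bundled
synthetic multi-shell phantom generator with exactly known ground truth.

## The science in brief

Thermal noise in complex MRI data is zero-mean Gaussian; after the
magnitude operation it is Rician, with a **noise floor**: pure noise has
mean `σ√(π/2) ≈ 1.2533 σ` instead of zero. Diffusion MRI encodes its
information in signal *attenuation*, so the most informative measurements
(high b, gradients parallel to fibres, CSF) sit at the floor and are
rectified — variance becomes bias.

The package implements:

* **MP-PCA** — eigenvalues of each patch Casorati matrix `X'X/M` are
  compared against the Marchenko–Pastur pure-noise bulk (width
  `4σ̂²√((N−p)/M)` plus a Tracy–Widom finite-size allowance); components
  above it are kept, the rest removed. Applied to magnitude data (|MPPCA|)
  or to complex data rotated to the real axis (MPPCA*).
* **NORDIC-style thresholding** — voxelwise variance normalisation by a
  noise σ map, then a single hard singular-value threshold calibrated by
  Monte Carlo on pure-noise matrices (patch rule `P³ ≥ 11N`).
* **Non-local means** — the classical per-volume filter, weights
  `exp(−max(d² − 2σ², 0)/h²)`.
* **Phase tools** — Tukey low-pass phase-field estimation (half-maximum
  radius 58% of Nyquist), rotation to the real axis, and complex (AVG*) vs
  magnitude (|AVG|) averaging of repeats.
* **Evaluations** — SNR and angular-CNR maps, spherical-harmonic angular
  power spectra (orders 0–8), zero-attenuation-ROI noise-floor statistics,
  raw-minus-denoised difference maps, gradient-alignment signal reordering
  and dynamic range, effective-resolution FWHM from standardized model
  residuals, DTI/DKI fits, wild-bootstrap uncertainty, and
  subset-convergence (scan-time) analysis.

## A worked example

```r
library(dmridenoise)

# an SNR-5 two-shell phantom with known truth
spec <- phantom_spec(grid_shape = c(36, 36, 18),
                     shells = list(c(1000, 48), c(2000, 24)),
                     n_b0 = 6, snr_b0 = 5, seed = 7)
gt  <- build_phantom(spec)
ds  <- add_complex_noise(gt$clean_signal, gt, seed = 11)   # complex data
mag <- as_magnitude(ds)                                    # |.| data
rot <- rotate_to_real(ds, true_phase_field(gt))            # real-rotated

den_mag  <- mppca_denoise(mag)$denoised    # |MPPCA|
den_cplx <- mppca_denoise(rot)$denoised    # MPPCA*

# noise floor in the zero-attenuation (ventricle-like) core, b = 2000
core <- gt$rois$csf_core
b2   <- shell_indices(ds, 2000)
for (d in list(raw = mag, mppca_mag = den_mag, mppca_cplx = den_cplx))
  print(roi_intensity_stats(d, core, sigma_ref = 1/5, volumes = b2)$mean_sigma)
```

```
[1] 1.24765       # raw magnitude: the Rayleigh floor, sqrt(pi/2) = 1.2533
[1] 1.254424      # |MPPCA|: variance removed, floor intact
[1] 0.0238053     # MPPCA*: the floor is gone
```

The numbers are σ-normalised mean intensities in a region with (almost) no
signal: raw magnitude and magnitude-domain denoising sit at the Rayleigh
mean, complex-domain denoising at zero — the core claim of the framework in
three lines.

```r
# does denoising help the tensor fit?
wm <- gt$rois$single_fibre | gt$rois$crossing | gt$rois$tissue
truth <- fit_dti(dwi_dataset(gt$clean_signal, gt$grad, gt$voxel_size,
                             "magnitude"), mask = wm)
accuracy_vs_reference(fit_dti(mag, mask = wm)$fa, truth$fa, wm)$pearson_r
accuracy_vs_reference(fit_dti(den_cplx, mask = wm)$fa, truth$fa, wm)$pearson_r
```

```
[1] 0.4500537     # raw FA correlation with ground truth
[1] 0.888375      # after complex-domain MP-PCA
```

A thin command-line front end over the same functions is installed at
`inst/cli/dmridenoise.R` (subcommands `simulate`, `rotate`, `denoise`,
`average`, `evaluate`; each writes a JSON provenance sidecar).

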