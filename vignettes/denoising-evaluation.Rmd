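---
title: "Denoising diffusion MRI and knowing whether it worked"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising diffusion MRI and knowing whether it worked}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dmridenoise)
```

## The problem

Thermal noise limits every diffusion MRI experiment. In the complex
reconstruction domain it is zero-mean Gaussian with equal variance in the
real and imaginary channels; after the magnitude operation it becomes
Rician, with a *noise floor* — the non-zero mean that pure noise acquires
under `|·|` (a Rayleigh distribution with mean `σ√(π/2) ≈ 1.2533 σ` and
mode `σ`). Because diffusion contrast is encoded as signal *attenuation*,
the measurements that carry the most information (high b-value, gradients
parallel to fibres, CSF-filled regions) are exactly the ones driven down to
the floor, where they are rectified: variance turns into positive bias,
dynamic range collapses, and downstream estimates such as mean diffusivity
are pulled away from the truth.

Denoising must therefore be judged on more than "the image looks smoother".
This package implements patch-based denoisers in both the magnitude and the
complex (real-rotated) domains and, just as importantly, the quantitative
criteria that distinguish what each one actually does: variance reduction,
noise-floor suppression, spatial-resolution cost, model-fit precision and
accuracy, and scan-time-reduction potential.

## The denoisers

**MP-PCA** (`mppca_denoise`). Every P×P×P patch of the 4-D data is
flattened into an M×N Casorati matrix (M = P³ voxels, N volumes). Under
pure noise the eigenvalues of `X'X/M` follow the Marchenko–Pastur law,
whose bulk has width `4σ²√(N/M)`; signal components stand above it.
`mp_threshold` scans the eigenspectrum for the smallest rank p such that
the trailing N−p eigenvalues fit inside the bulk, with
`σ̂²(p) = mean(trailing)`. Components beyond p are zeroed and the patch
reconstructed. Two details matter:

* *Finite-size edge allowance.* The asymptotic bulk width under-covers the
  largest eigenvalue of finite matrices (its fluctuations follow the
  Tracy–Widom law). We add `2·M^(-2/3) γ^(-1/6) (1+√γ)^(4/3) σ̂²` to the
  acceptance width — calibrated once across matrix geometries so that pure
  noise is assigned rank 0 in ≥99% of draws, while a planted component at
  the bulk edge is still detected. Without it, ~10% of pure-noise patches
  are assigned spurious rank.
* *No mean removal.* Casorati matrices are not mean-centred by default
  (matching the lineage of the reference implementation); `demean = TRUE`
  is available.

The same function serves two methods: applied to magnitude data it is
|MPPCA|; applied to complex data rotated to the real axis it is MPPCA*.
The algorithm is identical — the input domain is the experiment.

**NORDIC-style thresholding** (`nordic_denoise`). The MP assumptions
require spatially stationary noise, which multi-coil reconstructions
violate. NORDIC first divides the data voxelwise by a noise σ map, making
the noise unit variance everywhere, then hard-thresholds patch singular
values at the mean largest singular value of a pure-noise matrix of the
same size (a seeded Monte-Carlo estimate, `nordic_threshold`), and scales
back. The default patch keeps an 11:1 ratio of patch voxels to volumes
(`P³ ≥ 11N`), versus `P³ ≥ N` for MP-PCA.

**Non-local means** (`nlm_denoise`). A per-volume filter: each voxel is
replaced by a weighted mean over a search window, with weights
`exp(−max(d² − 2σ², 0)/h²)` where d² is the mean squared patch difference
and `h = h_factor·σ`. It is included as the exemplar of a magnitude-domain
method with no inter-volume model: strong variance reduction, strong
blurring, no help with the floor.

## Phase handling

Complex data are brought to the real axis by multiplying with the conjugate
of a smooth phase field and keeping the real channel
(`estimate_phase_field` + `rotate_to_real`). The estimator low-passes each
slice/volume with a radially symmetric Tukey window whose half-maximum
radius defaults to 0.58 of the Nyquist radius (taper width 0.2; both the
radius/diameter convention and the taper are exposed, since only the 58%
figure is standard). With an accurate phase the rotated data carry
signal + zero-mean Gaussian noise: magnitude-domain tools can then be run
*without* the noise floor.

One honest caveat discovered during development and worth stating plainly:
in regions with **no signal at all**, a *self-estimated* phase is itself a
function of the noise, and rotating by it partially rectifies the noise
(≈0.6σ mean instead of 0). Phantom evaluations of domain effects therefore
rotate with the generator's exact phase field (`true_phase_field`), so that
noise-floor conclusions are about the denoisers, not about phase-estimation
error; the estimator itself is validated separately against the generated
smooth fields (recovery within 0.05 rad RMS at SNR 30 on b=0 volumes, and
≥10× attenuation of high-frequency phase jitter).

## The synthetic phantom

`build_phantom` lays out, on a small grid, the compartments the evaluations
need, each with exactly known truth:

* a CSF-like ellipsoid, isotropic D = 3.0×10⁻³ mm²/s (FA 0) — the
  ventricle analogue where attenuation is maximal and the floor dominates;
  an interior *core* (≥4 voxels from any boundary) is labelled separately
  so window/patch methods are scored without partial-volume contamination;
* a coherent single-fibre block, eigenvalues (1.7, 0.2, 0.2)×10⁻³ mm²/s
  (FA ≈ 0.87), principal axis +x;
* a two-tensor 90° crossing block (equal fractions);
* generic anisotropic tissue whose orientation rotates 90° per 24 voxels
  (a fixed coherence length — heterogeneity must not vanish on larger
  grids) and whose diffusivity drifts ±20% across the grid, so that
  ground-truth MD has genuine spatial contrast (a constant-MD compartment
  would make MD correlations degenerate); a `fibre_domains` variant with
  independent orientations per 4-voxel block is available;
* zero-signal background (pure noise, used for Rayleigh/Gaussian checks).

Noise is single-effective-channel complex Gaussian (the post-SENSE1
premise): `clean·e^{iφ} + (ε_r + i ε_i)` with per-voxel σ, either uniform
or doubling toward the grid centre (`radial_gradient`, to stress variance
normalisation). `snr_b0` sets S0/σ in the reference tissue; the three
regimes of interest are ≈30, 15 and 5. Phase fields are per-slice
second-order polynomials, optionally with added white jitter. Repeats share
the clean signal exactly (no motion is simulated — alignment is assumed
done upstream).

What the phantom deliberately does **not** contain: anatomy, EPI
distortion, motion, eddy currents, physiological noise, multi-coil
non-central-χ statistics. Passing tests show the algorithms do what their
theory says under Gaussian/Rician noise; they do not certify behaviour
under real-data artefacts.

## Evaluation criteria

*Signal quality* — `snr_map` (mean/sd over b=0 volumes), `angular_cnr`
(per-shell contrast-to-noise: the variance of the spherical-harmonic
predicted signal over the residual variance with a (n−k) denominator; the
contrast term is bias-corrected by `σ̂²(k−1)/(n−1)` so pure noise scores
≈0), and `sh_power`/`power_change` (power per even SH order `P_l = Σ_m
c_lm²` of the shell attenuation, fitted to order 8 unregularised).

*Noise floor* — `roi_intensity_stats` (mean/mode/σ-normalised statistics in
a zero-attenuation ROI; KDE mode with Silverman bandwidth, plus a binned
histogram mode — the figure-style readout, insensitive to narrow
sub-populations, and a wide-kernel KDE mode whose peak location is stable where the Silverman-bandwidth argmax of a flat-topped distribution jitters), `difference_map` (Δ = raw − denoised: zero-centred when a
method removes only zero-mean fluctuation, positively shifted when it
removes the rectified floor), `reorder_by_alignment` + `dynamic_range`
(signal sorted by |g·v1|: rectification collapses the parallel–perpendicular
contrast; complex-domain denoising restores it).

*Spatial resolution* — `standardized_residuals` of a DTI (or DKI) fit,
then `estimate_fwhm`: per axis, the variance of adjacent-voxel differences
relative to the field variance identifies the Gaussian kernel with the same
autocorrelation, `σ_i² = −Δx²/(4 ln(1 − v_i/(2v0)))`,
`FWHM = σ√(8 ln 2)`. The lag-1 autocorrelation form
`FWHM = Δx√(−2 ln 2/ln ρ₁)` is the algebraically equivalent cross-check
(both must recover imposed smoothing of 1.5/2.5/4.0 voxels within 5%;
note the ACF of a kernel is √2 wider than the kernel — the constant here is
chosen so the *kernel* width is reported). `resolution_penalty` is the
percent FWHM change vs raw; `patch_size_sweep` pairs it with CNR gain
across patch sizes.

*Model fitting* — `fit_dti` (log-domain OLS by default, matching the wild
bootstrap formulation; WLS optional; signals clipped at 10⁻⁶ of the b0
level before the log, with the clip count reported — an important
diagnostic for real-rotated data, where noise can drive voxels negative),
`fit_dki` (22-parameter quadratic-in-b expansion, used for residuals),
`wild_bootstrap` (in-situ Rademacher sign-flips of HC2-leverage-rescaled
log-domain residuals, 250 replicates by default), `accuracy_vs_reference`
(Pearson r and SSE), `subset_convergence` (greedy maximin direction
subsets, seeded, then fit and score).

## Numerical and design choices

* Overlapping patches: default stride 1 with unweighted averaging of all
  covering patches; `center_only` reproduces non-overlapping behaviour.
  Edge patches are shifted inward so the rim is covered.
* σ̂ per patch is assigned to all patch voxels and aggregated like the data.
* Rician/Rayleigh reference moments are used throughout
  (`mean = σ√(π/2)`, `mode = σ` at zero signal).
* The KDE mode uses Silverman bandwidth; the binned mode uses 100 bins.
* SNR/CNR caps (default 10⁶) flag zero-variance voxels instead of
  returning infinities.
* Degenerate FWHM arguments (`v_i ≥ 2v0`) are clipped per volume; when
  ≥50% of volumes clip, the estimate is flagged low-confidence.
* All randomness (noise, thresholds, bootstrap, subsets) is seeded;
  repeats use consecutive seeds.
* Voxel indices are 1-based everywhere, the R convention.

## Problem sizes

The shipped evaluations run on desk-scale phantoms chosen as the package's
own study conditions: a 36×36×18 SNR-5 phantom with b = 1000 s/mm²
(48 directions — enough for an order-8 SH fit) and b = 2000 s/mm²
(24 directions, maximal attenuation) shells plus 6 b=0 volumes for the
noise-floor, accuracy and spectral evaluations; a 48³ single-shell phantom
for the patch-size sweep; 64³ fields with 30 volumes for the smoothness
oracle; and a 20×20×12 phantom with six repeats for the averaging
references. The NLM search radius is 2 in these runs (its floor behaviour
in a noise ROI is window-size independent; its cost is not).

## Known limitations

* The inverted-U (rise-then-fall) of CNR gain versus patch size reported
  on in-vivo data does not reproduce on this phantom: with purely thermal
  noise the MP threshold stays calibrated at every patch size (σ̂ within
  0.5% of truth from 5³ to 15³), so noise removal never degrades, and the
  cost of large patches appears as angularly *smooth* signal bias, which a
  variance-ratio CNR cannot register. The decline seen in vivo involves
  non-thermal variance (motion, physiology, preprocessing residuals) that
  the generator deliberately excludes. The resolution-penalty half of the
  trade-off (monotone decrease with patch size) reproduces cleanly.
* Magnitude-domain NLM does not improve MD accuracy at SNR 5 here (it
  raises the floor and adds orientation-correlated smoothing bias); this
  mirrors the reduced MD benefits of magnitude-domain processing at very
  low SNR rather than a defect of the implementation.
* The noise model is Rician (2-dof); non-central-χ generalisations are
  future work.
* Phase estimation is validated on smooth polynomial fields; pathological
  phase (fold-overs, wraps within a slice) is out of scope.
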