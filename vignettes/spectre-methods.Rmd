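---
title: "Ghost-corrected SENSE reconstruction with channel-wise MPPCA denoising"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ghost-corrected SENSE reconstruction with channel-wise MPPCA denoising}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Diffusion-weighted EPI suffers from two coupled artifacts. First, phase
inconsistencies between odd and even readout lines produce the Nyquist
(N/2) ghost — a half-FOV-shifted replica of the object along the
phase-encode axis. Scanner reconstructions remove the linear (1D) part of
this inconsistency, but residual higher-order 2D phase errors leave
visible ghosting. Second, diffusion weighting attenuates the signal
exponentially, so high-b-value images sit near the noise floor of the
magnitude operation.

Parallel-imaging-based 2D phase correction (PEC-SENSE) estimates the
odd-even phase difference by reconstructing the two line parities
separately. Splitting k-space doubles the effective acceleration, so the
parity reconstructions — and, through the phase-modified joint unfold, the
final image — pay a geometry-factor (g-noise) penalty that is most
damaging exactly where the signal is weakest. The pipeline implemented
here as `spectre` removes noise from the *complex channel data before
image formation* with Marcenko-Pastur PCA (MPPCA), so that the phase
correction operates on cleaner data and amplifies less noise. The package
also implements the seven comparison pipelines (`sense`, `sense_m`,
`sense_c`, `sense_ch`, `pecsense`, `pecsense_m`, `pecsense_c`) so the
contribution of each stage can be isolated.

## Signal model and reconstruction

All arrays use the layout `[x, y, z, coil, volume]` with `y` the
phase-encode axis. Fourier transforms are centered (DC at the 0-based
index `floor(N/2)`) and orthonormal, so white noise keeps its variance
across domains.

**Encoding.** The simulator applies the mono-exponential tensor model
`S(b, g) = S0 exp(-b g'Dg)` voxelwise, weights by smooth complex coil
sensitivities, multiplies odd-parity lines by `exp(i dphi(x, y))` (the
entire odd-even difference is assigned to the odd parity — a gauge
choice; only the difference is physical), keeps every R-th ky line
starting from the line set containing DC, and adds zero-mean complex
Gaussian noise, iid across samples with a Hermitian coil covariance.

**Aliasing.** The acquired ky samples of one x-column are mapped to the
reduced-FOV profile by a unitary `N/R x N/R` DFT, giving the exact model

    A[j] = R^(-1/2) * sum_p rho[y_p] * exp(-2i pi (r - c) p / R)

over the `R` folded rows `y_p = (j + p N/R) mod N`, with `r` the offset
of the first used line and `c` the DC index. The offset phase matters for
the parity children (offset `r` and `r + R` at spacing `2R`) and is
carried through `fold_phase()`; its correctness is pinned by brute-force
DFT oracles in the tests.

**SENSE.** Per aliased voxel the least-squares system `rho = (E^H E)^-1
E^H s` is solved over the folded positions, after prewhitening data and
sensitivities with the inverse lower Cholesky factor `D = L^-1` of the
coil noise covariance (`Psi = L L^H`), so no covariance weighting is
needed. The geometry factor is `g_j = sqrt([(E^H E)^-1]_jj [E^H E]_jj)`.
Voxels with condition number above `1e8` are zeroed and counted;
zero-sensitivity background is 0 with `NaN` g-factor.

**PEC-SENSE.** The raw phase-difference map is
`Arg(I_odd * Conj(I_even))` of the parity unfoldings (effective
acceleration `2R`). Rather than unwrapping and filtering the angle, the
complex product itself is smoothed with a 2D Gaussian (default FWHM 5
voxels) and its argument taken: this is magnitude-weighted and wrap-safe,
and smoothly extrapolates beyond the support mask (voxels whose magnitude
product exceeds twice its median over the noise-only region). Maps are
estimated per slice and per volume ("per EPI"); reusing the first
volume's map (`map_source = "b0"`) or averaging complex products across
volumes is available for SNR-starved data. The joint unfold stacks
`2 n_coils` equations per reduced voxel: even rows use `Cw`, odd rows
`Cw exp(i dphi)` at the folded positions.

## MPPCA denoising

At each voxel a sliding kernel (default 5x5x5) builds the Casorati matrix
`X` (kernel voxels x volumes). The eigenvalues of `(1/M) X^H X` below the
Marcenko-Pastur edge are attributed to noise: the smallest signal count
`p` is accepted when the `N - p` smallest eigenvalues satisfy
`lambda_{N-p} - lambda_1 <= 4 sqrt((N-p)/M) sigma2hat` with `sigma2hat`
their mean — the spread of a pure-noise spectrum. The consistency test
uses `<=` and clamps eigenvalues below `1e-12 lambda_max` to zero, so
exactly-low-rank data terminate at the true rank (with a strict `<` and
raw floating-point eigenvalues they would not). The top-`p` subspace
reconstructs the centre voxel only; at array edges the kernel shifts to
stay in bounds so the centre voxel always owns a row. When the kernel has
fewer voxels than volumes the analysis transposes, keeping the eigenvalue
count on the smaller dimension. Complex data are eigen-analysed directly
(no real/imaginary stacking); `sigma2hat` is the total (real + imaginary)
variance per complex sample, so prewhitened channels have `sigma = 1`.

Channel-wise denoising (`sense_ch`, `spectre`) applies this per coil to
the prewhitened aliased channel series. Post-reconstruction variants:

* *magnitude* (`_m`): MPPCA on `|image|`, then the method-of-moments
  Rician correction `sqrt(max(M^2 - 2 sigma^2, 0))` using MPPCA's own
  per-voxel noise map. Clamped voxels are recorded, and the tensor fit
  excludes nonpositive signals per voxel rather than flooring them — a
  machine-epsilon floor makes the log-signal -744 and destroys the fit.
* *complex* (`_c`): a smooth background phase (argument of a
  Gaussian-filtered copy of each volume, FWHM 8) is conjugated away,
  and MPPCA runs on the real projection of the flattened data; the output
  is rectified to magnitude for fitting. The projection is the package's
  simplified reading of decorrelated phase filtering: after flattening,
  the imaginary channel carries only noise, while the complex series
  still contains spatially smooth per-volume phase-correction residues.
  Denoising the complex data directly retains those residues as spurious
  signal components (observed kernel rank 19/49 versus 10/49 on the same
  data) and negates the advantage of avoiding signal rectification.

## Diffusion models

The tensor is fitted by iteratively re-weighted log-linear least squares
(weights = squared currently-predicted signal, initialised from the
unweighted fit, relative parameter tolerance `1e-6`, max 50 iterations)
on volumes with `b <= 1000` s/mm^2. The kurtosis model adds the 15
unique fourth-order terms (parameterised as `MD^2 W`, fitted linearly
with two reweighting passes); `MK` is the mean apparent kurtosis
`W_app / D_app^2` over the acquisition's nonzero-b directions rather
than a spherical integral, matching common practice for this sampling.
Predicted signals are floored at `1e-6` of their maximum inside the
reweighting so weights never vanish.

## The synthetic dataset and what it does and does not show

`simulate_raw()` defines the reference conditions:

* 64 x 64 x 8 grid, 8 coils on a ring (Gaussian lobes, FWHM 0.55 FOV —
  R = 2 g-factors near 1.05 and parity-split (R = 4) g-factors of 2-4,
  typical of practical arrays), R = 2.
* A free-diffusion cylinder with MD `2.0e-3` mm^2/s (the reference
  diffusivity of the physical phantom this emulates) plus an inner
  anisotropic core with eigenvalues `(1.7, 0.3, 0.3)e-3`; the object is
  kept clear of the first readout rows, which form the noise-only
  calibration region.
* Shells every 200 s/mm^2 up to 1000 plus 2000 and 3000, 6 directions
  each, 7 b = 0 volumes (49 volumes). The five low shells feed the
  tensor fit, as in the phantom validation protocol this emulates; the
  in-vivo style 3-shell protocol (`diffusion_protocol()`) is a config
  option. These sizes keep a full 8-pipeline comparison to a few minutes;
  the 112x110 and 120x118 matrix sizes of clinical protocols are config
  options.
* Polynomial 2D parity phase errors (defaults spanning ~0.8 rad across
  the FOV); per-volume jitter defaults to 0 but exercises the per-EPI
  correction when enabled.
* Correlated coil noise via the Cholesky factor of an AR(1)-type
  Hermitian covariance, with `sigma0 = 0.054` chosen once so the SENSE
  b = 0 replica SNR lands near 11.5, the phantom-scan regime of the
  validation study this package mirrors.

The phantom is piecewise constant, so its Casorati matrices are exactly
low-rank and MPPCA performs better than it can on textured tissue:
absolute SNR gains of the denoising pipelines are optimistic, and passing
the ordering tests demonstrates the *relative* behaviour of the
pipelines (ghost suppression, g-noise cost of phase correction,
floor-driven MD bias, denoising-order effects), not absolute in-vivo
performance. The simulator also omits relaxation, susceptibility
distortion, eddy currents, motion and partial Fourier, which is why the
evaluation focuses on quantities with simulated ground truth.

## Evaluation metrics

Replica SNR is the voxelwise mean/SD over the b = 0 volumes, averaged
over the foreground eroded by 2 voxels (the ROI choice is the package's;
any fixed ROI gives the same orderings). Accuracy is the signed mean
voxelwise error relative to ground truth (positive = underestimation, so
"underestimated by 23%" maps to +23); precision is the population-SD
coefficient of variation across voxels; both are evaluated over the
uniform free-diffusion compartment. The ghost-to-signal ratio divides
the mean magnitude over the object mask shifted by FOV/2 (minus the
object) by the mean over the object; with noise it is floor-limited, so
the ghost-suppression criteria are evaluated on noiseless simulations
where the alternating-phase model gives the closed-form check
`GSR = |tan(alpha)|` for a constant phase of `2 alpha`.

## Numerical choices and degenerate inputs

* Covariance estimation uses `1/N` without mean subtraction (noise-only
  samples are zero-mean by construction); rank-deficient estimates
  (eigenvalue below `1e-12` of the maximum) are an error advising a
  larger noise region; near-singularity in the Cholesky gets a
  `1e-12 * trace` Tikhonov jitter with a warning. The complex Cholesky
  factor is computed by the standard column-wise algorithm (base R's
  `chol()` is real-only).
* Unfolding condition threshold `1e8` flags degenerate coil geometries;
  counts are reported on the reconstruction object.
* An all-zero tensor yields MD = 0 and FA defined as 0; zero-mean voxels
  are excluded from NRMSE summaries; empty masks and all-zero magnitude
  images are errors, not silent NaNs.
* All randomness flows through explicit integer seeds; rerunning a
  pipeline on the same container writes byte-identical NIfTI maps.

## Limitations

The phase-filter simplification above, the polynomial form of the
simulated phase errors (the spatial form of real residual 2D errors is
scanner-specific), the voxelwise-independent fits (no spatial
regularisation, no positivity constraints), and the desk-scale problem
sizes are the main deviations from a full clinical pipeline. The
covariance is estimated once per dataset (`per_slice` estimation is not
implemented); the kurtosis estimator is an unconstrained two-pass WLS
rather than a constrained fit.
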