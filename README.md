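# spectre

Reconstruction pipelines for multi-coil diffusion-weighted EPI (DW-EPI),
for MR physicists and image-reconstruction researchers who need 2D
Nyquist-ghost correction in low-SNR diffusion data without paying the
full g-noise penalty of parallel-imaging-based phase correction.

EPI phase inconsistencies between odd and even readout lines create the
N/2 ghost; reconstructing the two line parities separately (at twice the
acceleration) yields a 2D phase-difference map that corrects the ghost in
a joint SENSE unfold (PEC-SENSE), but the doubled acceleration amplifies
noise exactly where diffusion attenuation has already consumed the
signal. The `spectre` pipeline denoises the *complex channel data before
image formation* with Marcenko-Pastur PCA (MPPCA), so the phase
correction operates on cleaner data:

1. **Prewhitening** — estimate the coil noise covariance Ψ from a
   noise-only region, factor Ψ = LLᴴ, and apply D = L⁻¹ to channel data
   and sensitivities so channel noise is iid unit-variance.
2. **Channel-wise MPPCA** — per coil, sliding 5×5×5 Casorati matrices
   X (voxels × volumes); eigenvalues of (1/M)XᴴX below the
   Marcenko-Pastur edge (spread ≤ 4√(γ)·σ̂², γ = (N−p)/M) are noise;
   the top-p subspace reconstructs the centre voxel and σ̂ is the local
   noise level.
3. **PEC-SENSE** — per slice and volume, Δφ(x,y) = Arg(I_odd·conj(I_even))
   from the parity unfoldings, smoothed wrap-safely via the complex
   product; the joint unfold stacks even rows C and odd rows C·exp(iΔφ),
   solved by least squares with g-factor maps
   g = √([(EᴴE)⁻¹]ⱼⱼ·[EᴴE]ⱼⱼ).

Seven comparison pipelines (`sense`, `sense_m`, `sense_c`, `sense_ch`,
`pecsense`, `pecsense_m`, `pecsense_c`) isolate each stage: `_m`/`_c`
denoise magnitude (with method-of-moments Rician debiasing) or
phase-flattened complex data after image formation; `_ch` denoises
channels without phase correction. Diffusion tensor (IRLS) and kurtosis
(two-pass WLS) fits produce MD/FA/MK maps, and the evaluation module
computes replica SNR, signed relative MD error, coefficient of variation
and a ghost-to-signal ratio against the simulator's ground truth.

## Worked example

Simulate the reference dataset (64×64×8 grid, 8 coils, R = 2, multi-shell
protocol, polynomial 2D parity phase errors, correlated coil noise at a
phantom-scan SNR) and compare four pipelines:

```r
library(spectre)
raw <- simulate_raw(seed = 1)
rep <- compare_pipelines(raw, c("sense", "pecsense", "pecsense_c", "spectre"))
rep[, c("pipeline", "snr", "md_mean", "md_cov", "md_err_pct", "gsr")]
```

```
    pipeline    snr  md_mean md_cov md_err_pct    gsr
1      sense 10.271 0.001964  8.595      1.783 0.0915
2   pecsense  8.937 0.001561 23.467     21.945 0.1002
3 pecsense_c 16.498 0.001936 14.808      3.175 0.0505
4    spectre 85.130 0.001985  3.074      0.744 0.0301
```

Reading the table: the 2D phase correction alone (`pecsense`) costs SNR
(8.9 vs 10.3) and, through the amplified noise floor in the
diffusion-weighted volumes, underestimates the true MD of
2.0×10⁻³ mm²/s by ~22% with a 23% CoV across voxels. Denoising the
reconstructed complex data (`pecsense_c`) recovers much of that;
denoising the channels *before* the phase correction (`spectre`) brings
MD within 1% of truth at a 3% CoV while also suppressing the ghost
(`gsr`, mean ghost-to-object intensity ratio of the b=0 image).

The same functions reproduce the published benchmark arithmetic, e.g.

```r
tab <- published_benchmarks()
accuracy_mean_relative_error(
  array(tab$md_mean[tab$pipeline == "pecsense"], c(1, 1, 1)),
  tab$md_mean[tab$pipeline == "reference"])$signed
#> [1] 23
```

A thin CLI chains the stages (`inst/cli/spectre`):

```sh
spectre all --out run1 --seed 7                      # simulate + recon + fit + eval
spectre recon --raw run1/raw.rds --pipeline spectre --save-phase-maps
spectre eval --raw run1/raw.rds --pipelines sense,pecsense,spectre
```

Outputs are NIfTI-1 (images, g-factor, Δφ, MD/FA/MK/NRMSE maps),
FSL-style `bvals`/`bvecs`, CSV/JSON reports, and an RDS raw-data
container holding k-space, sampling mask, parity labels, sensitivities,
noise samples, protocol and ground truth.

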