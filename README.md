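# dktihist

Diffusion kurtosis tensor imaging (DKTI) metrics with quantitative
histology texture correlation.

Water diffusion in brain tissue is non-Gaussian: membranes and myelin
restrict displacement, and the *kurtosis* of the displacement
distribution indexes that microstructural heterogeneity. `dktihist` is
for researchers who want to (a) estimate the diffusion tensor `D` and
kurtosis tensor `W` from multi-shell diffusion-weighted MRI, (b) derive
the eight regional scalar metrics, (c) quantify fiber-orientation
heterogeneity in stained histological sections with a tiled
histogram-of-oriented-gradients (HOG) statistic, and (d) correlate the
two modalities region-by-region.

## The model

For b-value `b` and unit gradient direction `n`,

    ln S(b, n) = ln S0 − b · D_app(n) + (b²/6) · MD² · W_app(n)

with `D_app(n) = Σ nᵢnⱼDᵢⱼ`, `W_app(n) = Σ nᵢnⱼnₖnₗWᵢⱼₖₗ` and
`MD = tr(D)/3`. `dki_fit()` solves the 22 unknowns (ln S0, 6 elements of
`D`, 15 elements of `MD²·W`) by linear least squares on log-signals and
returns a classed fit object with `print`, `summary`, `coef`, `predict`,
`residuals`, `fitted` and `simulate` methods. Derived per voxel:

| metric | definition |
|---|---|
| D_mean, D_axial, D_radial | eigenvalue mean, λ₁, (λ₂+λ₃)/2 |
| FA | normalized eigenvalue dispersion of `D`, 0–1 |
| K_mean | spherical average of K_app(n) (250-direction quadrature) |
| K_axial, K_radial | K_app along / averaged perpendicular to the axis |
| KFA | ‖W − W̄·I⁽⁴⁾‖_F / ‖W‖_F, 0–1 |

The histology statistic tiles a grayscale section into 100-μm tiles,
computes an 8-bin, 20-px-cell, 2×2-block L1-normalised HOG per tile, and
summarises each tile's feature vector by its SD and excess kurtosis —
coherent parallel fibers concentrate gradient orientations and raise the
kurtosis; mixed orientations flatten it. Regional imaging and histology
metrics are then correlated (Pearson, Benjamini–Hochberg corrected).

Synthetic generators (`simulate_dwi_phantom()`,
`generate_fiber_texture()`) produce multi-region DWI phantoms with
Rician noise and von Mises fiber textures so the whole chain runs
without external data.

## Worked example

Fit a white-matter-like voxel at SNR 40 and read off its metrics:

```r
library(dktihist)
scheme <- default_scheme()          # b = 0/100/1000/2000, 30 directions
wm  <- build_tensors(region_spec("splenium", "WM", 1.10e-3, 0.35e-3,
                                 k_mean = 1.17))
sig <- forward_dki_signal(1000, wm$dt, wm$kt, scheme)
set.seed(42)
fit <- dki_fit(add_rician_noise(sig, 1000 / 40), scheme)
summary(fit)
#> Diffusion kurtosis fit (91 measurements)
#>   s0: 1005   MD: 0.0006314 mm^2/s   residual norm: 0.3431
#> Derived metrics:
#>   D_mean 0.631  D_axial 1.164  D_radial 0.365 (x1e-3 mm^2/s)
#>   K_mean 1.308  K_axial 1.112  K_radial 1.189
#>   FA 0.630  KFA 0.677
```

The true voxel has D_mean 0.60 ×10⁻³ mm²/s and K_mean 1.17; a single
noisy realisation lands within a few percent of both, and FA ≈ 0.63
reflects the strong axial anisotropy (λ∥/λ⊥ ≈ 3). The full dual-modality
pipeline on synthetic inputs:

```r
res <- run_end_to_end(pipeline_config(seed = 6), outdir = "out")
subset(as.data.frame(res$correlations),
       dkti_metric == "d_mean" & histo_metric == "histo_kurtosis")
#>   dkti_metric   histo_metric n        r          p      p_adj
#> 1      d_mean histo_kurtosis 8 0.805941 0.01571422 0.02934195
```

Eight synthetic ROIs grade from coherent, low-diffusivity WM-like tissue
to mixed-orientation SCN-like tissue; regional mean diffusivity and
histological kurtosis fall together across that gradient, so the planted
pair is detected (r ≈ 0.8 here) and survives the BH correction.

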