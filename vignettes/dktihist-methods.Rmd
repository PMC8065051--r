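---
title: "Models and methods behind dktihist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dktihist}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dktihist)
```

## The problem

Water diffusion in brain tissue deviates from a single Gaussian
displacement distribution wherever membranes, myelin and organelles
restrict movement. Diffusion kurtosis imaging quantifies that deviation:
alongside the rank-2 diffusion tensor $D$ it estimates a fully symmetric
rank-4 kurtosis tensor $W$, whose directional projections measure
microstructural heterogeneity. `dktihist` implements the full analysis
chain for relating these imaging metrics to quantitative histology:
tensor estimation and scalar maps, regional statistics, a
histogram-of-oriented-gradients (HOG) texture statistic for stained
sections, and the regionwise cross-modality correlation, plus synthetic
generators that make every stage testable without scanner or slide data.

## Signal representation and estimation

For a measurement with b-value $b$ and unit gradient direction $n$ the
log-signal is modelled by the two-term cumulant expansion

$$\ln S(b, n) = \ln S_0 \; - \; b\, D_{app}(n) \; + \;
  \frac{b^2}{6}\, \overline{D}^2\, W_{app}(n),$$

with $D_{app}(n) = \sum_{ij} n_i n_j D_{ij}$,
$W_{app}(n) = \sum_{ijkl} n_i n_j n_k n_l W_{ijkl}$ and
$\overline{D} = \mathrm{tr}(D)/3$. The directional (apparent) kurtosis is
$K_{app}(n) = (\overline{D}^2 / D_{app}(n)^2)\, W_{app}(n)$.

`dki_fit()` estimates the 22 unknowns ($\ln S_0$, 6 elements of $D$, 15
elements of $\overline{D}^2 W$) by ordinary linear least squares on
log-signals, then recovers $W$ by dividing by the fitted
$\overline{D}^2$. Reasons for this choice:

* it is exact on noiseless data (the round-trip tests demand recovery to
  better than $10^{-6}$ relative error and observe $\sim 10^{-14}$);
* it is a single linear solve shared by every voxel of a volume, which
  makes `fit_dki_volume()` one matrix solve for the whole grid;
* weighting and positivity constraints add little at the SNR regimes the
  package targets (median regional errors at SNR 40 stay well inside
  10%, see the phantom tests).

A constrained mode (`constrained = TRUE`) shrinks the fitted $W$ toward
its isotropic part until directional kurtosis over the packaged
quadrature grid lies in $[0, k_{max}]$, for users who want the behaviour
of constrained estimators; the unconstrained linear fit is the default
because constraint settings of reference tools vary and are rarely
reported.

Degenerate voxels are flagged, never zero-filled: non-positive signals,
fitted $\overline{D} \le 10^{-12}$ mm²/s (the numerical-zero floor), or
a non-positive-definite fitted $D$ mark a voxel invalid, its metrics are
`NA`, and ROI statistics exclude it. The zero diffusion tensor has FA
defined as 0, and the zero kurtosis tensor KFA 0, so regional means
never absorb NaNs from exactly-degenerate synthetic inputs.

## Scalar metrics

Eight scalars are derived per voxel:

* $\overline{D}$ (mean), axial and radial diffusivity, FA (from the
  eigenvalues of $D$);
* mean, axial and radial kurtosis and KFA (from $D$ and $W$).

**Mean kurtosis** is the spherical average of $K_{app}(n)$. There is no
elementary closed form, so the package integrates numerically over a
fixed 250-direction near-uniform set (electrostatic-repulsion layout,
shipped in `inst/extdata/sphere250.tsv`). The grid integrates degree-4
monomials to about $10^{-4}$ relative error; against a $10^6$-direction
Monte-Carlo average the quadrature agrees within 0.5% on random
brain-like tensors (tested). Because the grid is fixed, $k_{mean}$ is
rotation invariant only to the quadrature accuracy — the test suite
checks rotation agreement at 0.5% for $k_{mean}$ and at $10^{-8}$ for
the closed-form metrics.

**Axial/radial convention.** Two conventions are implemented behind
`axis_convention`: the literature-standard `principal_eigenvector`
(axial along $e_1$, radial the average over the perpendicular great
circle, 64 equally spaced directions) and `anteroposterior` (axial along
the image y axis), which some regional workflows prefer for elongated
anteroposterior structures. The default is `principal_eigenvector`
because it is intrinsic to the tensor and rotation-equivariant;
`d_mean`, FA, $k_{mean}$ and KFA are identical under both.

**KFA** is $\lVert W - \bar W\, I^{(4)}\rVert_F / \lVert W \rVert_F$
with $\bar W = \tfrac15 (W_{1111} + W_{2222} + W_{3333} + 2W_{1122} +
2W_{1133} + 2W_{2233})$ and $I^{(4)}$ the symmetric isotropic rank-4
tensor; norms are over the full 81-element expansion. The identity
$\lVert W - \bar W I^{(4)}\rVert_F^2 = \lVert W\rVert_F^2 - 5\bar W^2$
makes this a two-line computation; tests verify it against the explicit
81-element expansion.

## Map pipeline

`smooth_dwi()` reproduces the standard pre-fit smoothing: separable
Gaussian convolution with $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$
converted to voxel units (default FWHM 3 mm per axis), followed by a
3×3×3 median filter. Borders are replicate-padded so constant volumes
pass through unchanged. Smoothing is applied to signals before fitting
(the documented behaviour of the reference mapping tool); smoothing
fitted maps instead is possible by calling the filters on the metric
arrays. The median kernel size (3) is a package default — reference
tools do not document theirs.

Tissue probability maps become masks by strict thresholding
(`probability > 0.95` by default); strictness at the boundary is a
package decision since "threshold 95%" conventions differ. ROI
statistics use the sample SD ($n-1$), SEM over voxels, and
across-subject aggregation as the unweighted mean of per-subject ROI
means (voxel counts differ across subjects, and subjects — not voxels —
are the unit of inference), with CV = SD/|mean|·100.

## Histology heterogeneity

`compute_hog()` follows the classic tile/cell/block protocol on
grayscale ROI images (RGB converted with luminance weights
0.2125/0.7154/0.0721; silver stains are dark-on-light, so no inversion):

1. non-overlapping square tiles of 100 μm (side in pixels =
   `round(tile_um / pixel_size)`, partial border tiles discarded);
2. first-order gradients by central differences; unsigned orientations
   on $[0°, 180°)$, 8 bins, hard assignment, magnitude-weighted, pooled
   over 20×20-px cells;
3. contrast normalisation over 2×2-cell blocks with the L1 norm
   (stabiliser $10^{-12}$), sliding one-cell stride, concatenated into
   one feature vector (19×19×4×8 = 11 552 entries for a 400-px tile).

The tile's heterogeneity metrics are the SD and the kurtosis of the
feature-vector entries. Kurtosis uses the excess (Fisher) convention
$m_4/m_2^2 - 3$ by default — the default of the common scientific
stacks — with the Pearson convention behind a flag. Unsigned gradients
and the sliding-block stride follow the de-facto reference
implementation of the descriptor; a non-overlapping stride is available
in `hog_config()`.

Block-level L1 normalisation makes the statistic essentially invariant
to global brightness scaling (tested: < 1% change over 0.5–2×), which is
its purpose: slide illumination and stain depth vary.

ROI values average non-degenerate tiles (all-constant tiles are flagged
degenerate and excluded); tissue-class values average member ROIs, with
a pooled-tiles mode behind a flag since aggregation conventions for
tissue-level reporting are ambiguous in practice.

## Cross-modality statistics

`correlate_modalities()` computes Pearson's r (p from the t transform
with $n-2$ df) for every (imaging metric, histology metric) column pair
of the ROI table and applies Benjamini–Hochberg correction across the
full family of pairs tested in one invocation — the family definition is
explicit because it changes adjusted values. Pairs with fewer than 3
complete rows or zero variance are skipped and reported. Under a
planted null the BH-adjusted discovery rate stays at the nominal 5%
(tested over 150 simulated families).

## Synthetic generators

**DWI phantom.** `region_spec()` fixes a region's ground truth as an
axially symmetric diffusion tensor (eigenvalues
$\lambda_\parallel, \lambda_\perp, \lambda_\perp$) plus a kurtosis
target. Two constructions are available:

* a $(K_\parallel, K_\perp)$ pair — the minimal axially symmetric $W$
  whose directional kurtosis equals $K_\parallel$ on the axis and
  $K_\perp$ (constant) on the perpendicular great circle, with a
  built-in closure check to $10^{-9}$;
* a single $k_{mean}$ target — $W = (k/\overline{D}^2)\,
  \mathrm{sym}(D \otimes D)$, which makes $K_{app}(n) \equiv k$ exactly,
  so the spherical mean is $k$ by construction while KFA remains
  positive for anisotropic $D$.

The default four-class phantom uses the constant-$K$ construction at
regional values typical of healthy-brain reports: WM
($\overline{D} = 0.60 \times 10^{-3}$ mm²/s, $K = 1.17$, FA ≈ 0.62), GM
(0.80, 0.82, FA ≈ 0.21), CSF (2.07, 0.74, FA ≈ 0.12) and WM-like SCN
(0.46, 1.17), on a 40×40×16 grid of axis-aligned boxes (2-mm slices).
Rician noise is the MRI-realistic default:
$S' = \sqrt{(S+\epsilon_1)^2 + \epsilon_2^2}$,
$\epsilon \sim N(0, (S_0/\mathrm{SNR})^2)$, all randomness through one
seeded generator recorded in the output. What the phantom does *not*
emulate: anatomy, partial-volume gradients (boxes have sharp borders),
eddy-current or motion artefacts, and CSF pulsation — recovery results
on it therefore demonstrate correctness of the estimator chain, not
robustness to scanner physics.

**Fiber textures.** `generate_fiber_texture()` rasterises dark line
segments on a light background; orientations follow a von Mises
distribution through the doubled-angle construction (axial data on
$[0°, 180°)$), sampled by Best–Fisher rejection. $\kappa = 32$ gives
near-parallel fibers (circular SD ≈ 5°), $\kappa = 0$ uniform
orientations. Defaults: 512-px images at 0.25 μm/px, fiber length
75–125 μm (spanning a full 100-μm tile, as parallel subcortical fibers
do), ~0.5 μm width, and a fiber count scaled with image area
(600 per 512² px).

The density and length defaults matter scientifically: the HOG
feature-vector kurtosis discriminates orientation coherence in the
dense, tile-spanning regime (coherent > mixed, monotone in $\kappa$ —
the analogue of coherent white matter scoring above mixed-orientation
subcortical tissue). In a sparse short-fiber regime the statistic is
instead dominated by per-cell magnitude heterogeneity and the ordering
can invert; that behaviour is a property of the descriptor itself (we
reproduced it with an independent reference implementation), which is
why the generator pins the dense regime by scaling fiber count with
area. Passing coherence tests on these textures shows the descriptor
chain is computed correctly and responds to orientation dispersion; it
does not show that real stained sections sit in the same regime — with
real slides, stain density and artefacts co-vary with tissue class.

## Numerical choices and problem sizes

* Quadrature: 250 fixed directions for $k_{mean}$, 64 great-circle
  directions for radial metrics.
* Degenerate handling: strict flags plus the FA/KFA := 0 conventions for
  exactly-zero tensors.
* Tie-breaks: eigenvector signs fixed (largest-magnitude component
  positive) so outputs are deterministic.
* Test problem sizes: 100-draw round trips, a $10^6$-direction
  Monte-Carlo oracle for the spherical average, the 40×40×16 phantom at
  SNR 40, 20 seeds × 4 concentrations for the coherence ordering, and an
  8-ROI end-to-end run on a 24×24×8 grid — sizes chosen to exercise each
  claim at comfortable statistical resolution while keeping the default
  suite fast on one CPU.

## Known limitations

* No Rician noise-floor correction: at very high b or very low SNR the
  magnitude floor biases kurtosis upward; the package targets SNR ≈ 40
  protocols where the phantom tests show ≤ 10% median regional error.
* The closed-form mean-kurtosis expression (elliptic integrals) is not
  implemented; quadrature accuracy (0.5%) bounds $k_{mean}$ fidelity.
* No registration, segmentation or distortion correction: imaging inputs
  are assumed co-registered, probability maps and ROI masks are inputs.
* Histology: no stain deconvolution or cell counting; single-resolution
  regions only.
* Correlation analysis is ROI-level and assumes independent regions; no
  mixed-effects structure across subjects.
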