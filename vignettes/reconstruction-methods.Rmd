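---
title: "Freehand 3D ultrasound reconstruction by local polynomial kernel regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Freehand 3D ultrasound reconstruction by local polynomial kernel regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Freehand 3D ultrasound sweeps a tracked 2D probe over the body by hand.
Each captured B-scan `I_i` comes with a rigid pose `T_i` (position +
orientation from an external tracker, already calibrated to the image
plane), so every pixel has a known position in space — but the set of
pixels is irregular and sparse: slices are unevenly spaced, tilted, and
may intersect. Volume reconstruction turns this scattered data into a
regular voxel grid that can be resliced, rendered and measured.

`usrecon` implements a two-stage reconstruction:

1. **Bin-filling.** Pixel `(u, v)` of frame `i` maps to the physical
   point `M_i · (u·s, v·s, 0, 1)ᵀ`, where `M_i` is the 4×4 homogeneous
   pose and `s` the pixel size in mm. The point is snapped to its nearest
   voxel; voxels hit more than once average their contributions. The
   continuous (unsnapped) voxel-space positions and intensities are kept
   as a sample cloud `{(Xᵢ, Yᵢ)}`.
2. **Kernel regression.** The cloud is modelled as `Yᵢ = r(Xᵢ) + εᵢ`
   with i.i.d. zero-mean noise. At each voxel centre `X`, `r` is
   approximated by an order-N Taylor polynomial in `Xᵢ − X` and fitted by
   weighted least squares,

   β̂ = argmin Σᵢ wᵢ (Yᵢ − 𝕩ᵢᵀβ)², wᵢ = exp(−‖Xᵢ − X‖² / 2h²),

   over samples within the window cube. The voxel value is the fitted
   intercept `e₁ᵀβ̂ = e₁ᵀ(𝕏ᵀW𝕏)⁻¹𝕏ᵀW𝕐`. For N = 0 this reduces to the
   Nadaraya–Watson weighted mean; N = 1 and 2 add linear and quadratic
   structure that lets the estimator track intensity gradients and curved
   boundaries instead of blurring them.

The Gaussian kernel concentrates weight near the voxel, so the estimator
suppresses speckle (a weighted local average) while the polynomial terms
preserve boundaries (local trends are fitted, not flattened). That is the
trade-off the baselines get wrong in one direction or the other: VNN
copies the nearest pixel (sharp but artifact-prone), PNN averages into
bins then fills holes from neighbourhoods (blurring), DW averages with
inverse-distance weights (blurring).

## Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `order` | polynomial order N of the local fit | 1 | — |
| `window` | cube edge R of the neighbourhood | 15 | voxels |
| `bandwidth` | Gaussian kernel scale h | 0.5 | voxel units |
| `min_samples` | minimum neighbours for a full-order fit | basis length (1/4/10) | — |
| `cond_limit` | condition ceiling of the normal equations | 1e8 | — |
| `fallback` | behaviour of ill-posed voxels | `order_zero` | — |
| `preserve_filled` | keep bin-filled voxels untouched | `FALSE` | — |

The defaults N = 1, R = 15, h = 0.5 are the reference settings for the
method. Choices the method statement leaves open were fixed as follows:

* **R is a cube edge in voxels.** The neighbourhood is the cube of edge
  R centred on the target (half-width (R−1)/2), enumerated over the voxel
  cells; a cube, not a sphere, is what an `O(R⁶)`-flavoured per-voxel
  cost implies, and it is the natural unit for cell-binned search.
* **h is in voxel units on an isotropic grid.** The general estimator
  carries a 3×3 bandwidth matrix that reduces to a single scalar once the
  covariates share a common scale; expressing sample positions in voxel
  units of an isotropic grid is exactly that normalisation, so one scalar
  h is meaningful.
* **All voxels are re-estimated by default**, including bin-filled ones:
  the regression stage is an estimate of the whole volume, and
  re-estimating sampled voxels is what gives speckle suppression at the
  data locations themselves. `preserve_filled = TRUE` restores the
  interpolation-only behaviour.
* **Bin-fill collisions average.** Averaging is the symmetric,
  order-independent choice (the alternatives — maximum, most recent,
  first — all depend on scan order or bias the intensity).

## Numerical choices

* **Weight rescaling.** All weights are multiplied by
  `exp(+d²_min / 2h²)` (d_min = distance to the nearest neighbour), a
  constant factor that cancels exactly in the WLS solution but keeps the
  largest weight at 1. Without it, a small h underflows every weight and
  the estimator would return 0/0; with it, h → 0⁺ cleanly recovers the
  nearest-neighbour value and h → ∞ the plain mean.
* **Ill-posed neighbourhoods.** The normal equations are screened by a
  1-norm reciprocal-condition estimate; if `rcond < 1/cond_limit`, the
  system is rank-deficient for practical purposes (e.g. all neighbours
  coplanar, leaving an out-of-plane slope free) and the voxel falls back
  to the order-0 weighted mean (or is left empty, by configuration). A
  voxel with no sample in its window is always empty → value 0, excluded
  from the filled mask.
* **Deterministic snapping.** Half-way rounding ties go toward the lower
  voxel index, fixed so bin-filling is reproducible across platforms.
* **Tie-breaks.** VNN and the DW zero-distance rule break exact distance
  ties by lowest frame id, then input order, making all baselines
  invariant to sample order.
* **Reslicing** uses trilinear interpolation; pixels mapping outside the
  volume are excluded from the RMSE mean rather than scored against 0,
  so the metric measures reconstruction quality, not bounding-box
  coverage.

## The synthetic sweep generator

No scan data accompanies the method, so validation runs on simulated
sweeps with known ground truth. `make_phantom()` renders spheres,
ellipsoids and slabs on a constant background; `simulate_sweep()` marches
a virtual probe along z, perturbing each frame by seeded random tilts
(std `tilt_jitter`, degrees) and offsets (std `offset_jitter`, mm) to
emulate freehand irregularity — frames end up non-parallel and may
intersect — and samples pixel intensities from the phantom by trilinear
interpolation. Speckle is emulated by multiplicative Gaussian noise,
`out = in · (1 + σg)` clipped at zero: the regression model assumes only
zero-mean noise, and this surrogate is seed-reproducible and sufficient
to exercise the smoothing-versus-detail trade-off. It is **not** a
physical ultrasound model — no Rayleigh statistics, point-spread
function, attenuation or shadowing — so passing tests demonstrate
correct scattered-data estimation, not clinical image quality.

The default fixture is 40 frames of 64×64 pixels at 1 mm/pixel through a
64³ phantom with spherical inclusions, nominal slice step 1.5 mm, tilt
jitter 2°, offset jitter 0.3 mm, speckle σ = 0.1 — a scaled-down version
of a real phantom sweep (the reference experiment used 102 frames of
400×400 at 0.5 mm/pixel), sized so a full four-method comparison runs in
minutes on one core. Jitter magnitudes are typical of a steady hand-held
sweep: a couple of degrees of wobble and sub-millimetre drift per frame.

## Evaluation protocol

`leave_one_out()` removes one B-scan, reconstructs from the rest on a
grid bounding the full sweep, reslices the volume at the removed frame's
pose and scores RMSE against the removed image over in-volume pixels. A
good reconstructor predicts the held-out slice from its neighbours. On
the default fixture the expected ordering is KR lowest, and the
acceptance suite asserts exactly that (`rmse(kr) < rmse(vnn)`,
`< rmse(pnn)`, `< rmse(dw)`); the package makes no claim about absolute
RMSE values, which depend on the fixture.

Two floors anchor the pipeline: an affine intensity field swept
noiselessly must reconstruct with RMSE < 1e-3 (order-1 polynomial
reproduction propagated end to end — in practice it comes back at
~1e-12), and a duplicated slice must be recovered exactly by VNN.

## Problem sizes

Unit tests run on 8³–16³ grids with clouds of tens to hundreds of
samples, where brute-force oracles (direct normal-equations solves,
exhaustive nearest-neighbour scans, per-pixel RMSE loops) are feasible;
the acceptance experiment runs the full default fixture (≈315k voxels,
≈164k samples, four methods, about two minutes of kernel regression on
one core). These sizes were chosen to keep the whole suite interactive
while leaving the estimator's per-voxel mathematics identical to any
larger run.

## Known limitations

* Bandwidth is global and fixed; no automatic or spatially adaptive
  selection.
* Gaussian kernel only; square pixels and isotropic voxels only.
* The PNN hole-filling variant (mean, growing window) and the DW radius
  (3 voxels) are reasonable fixed choices, not tuned reproductions of any
  particular published variant.
* Calibration is out of scope: poses are trusted as given (after a
  1e-4 orthonormality check and polar-decomposition cleanup on load).
* Spline/RBF, probe-trajectory, fast-marching and adaptive-DW
  reconstructors are not implemented.
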