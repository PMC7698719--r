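---
title: "Quantitative contrast-enhanced micro-CT analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative contrast-enhanced micro-CT analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cemct)
```

## Scope

`cemct` implements the quantitative analysis chain used in preclinical
contrast-enhanced (CE) X-ray imaging of tumor vasculature in small-animal
models: static single-energy (SE) and dual-energy (DE) micro-CT
quantification of enhancement ($E$), iodine concentration ($C_I$) and
relative blood volume (rBV), and a dynamic contrast-enhanced (DCE) planar
protocol quantifying rBV and the volume transfer constant $K^{trans}$ by
Patlak analysis, followed by the statistical stage correlating imaging
parameters with histological biomarkers of angiogenesis (percent necrosis,
proliferation index, microvessel density).

Because no real image data ship with the package, a first-class synthetic
generator (`phantom_spec()`, `make_se_pair()`, `make_de_pair()`,
`make_dce_series()`, `make_calibration_phantom()`,
`make_histology_table()`) produces every input of the pipeline with known
ground truth, which is what the test suite and the acceptance report
exercise end to end.

## Image model and static pipeline

A `cemct_volume` is a 3D scalar array with voxel spacing (mm), a
frame-of-reference id, a value-kind tag and an optional protocol tag. The
value kind encodes the position in the processing chain and only the
pipeline operations may advance it:

`attenuation_mu` $\to$ (`hu_calibrate`) $\to$ `hu` $\to$ (`subtract`)
$\to$ `enhancement_hu` $\to$ (`apply_calibration`) $\to$ `iodine_mg_ml`.

* **HU calibration.** $HU = 1000\,(\mu - \mu_w)/\mu_w$ with the water
  attenuation $\mu_w$ of each beam quality. Water maps to 0, vacuum to
  $-1000$.
* **Subtraction.** Temporal mode forms $E = CE - baseline$; dual-energy
  mode forms $E = HE - \alpha\,LE$ with $\alpha = 0.55$ by default, the
  weighting that cancels unenhanced soft tissue (not bone) between the two
  beam qualities.
* **Iodine calibration.** $C_I = a\,E + b$ per protocol, with $a, b$
  fitted by ordinary least squares against an iodinated phantom with known
  concentrations (at least three distinct). The intercept is left free:
  whether the physical calibration passes through the origin is
  protocol-dependent and unknowable in general, so the package reports it
  together with $R^2$ rather than forcing $b = 0$. Negative $C_I$ voxels
  are retained by default so VOI means stay unbiased (clamping is opt-in).

Coordinates: voxel indices are 0-based and the world coordinate of a voxel
center is `index * spacing` from the corner voxel. All VOI geometry lives
in world (mm) coordinates.

## Registration

Baseline images must be registered to CE images (and LE to HE) before
subtraction. No general-purpose registration library is available in the
target environment, so the package implements intensity-based affine
registration directly: normalized cross-correlation (NCC) over the valid
overlap, optimized with Nelder–Mead across a block-averaged
multi-resolution pyramid (factors 4, 2, 1 by default), a translation-only
stage seeding the 12-parameter affine stage, with simplex restarts per
level. Both inputs are pre-smoothed with a separable $[1,2,1]/4$ kernel
(two passes) — sharp-edged images make the NCC landscape ragged under
linear interpolation. Full-resolution iterations are capped because each
metric evaluation there costs $f^3$ times a coarse-level one.

The contract is parameter recovery, not a particular optimizer: the
acceptance suite applies a known 2-voxel translation and a known small
affine (5° rotation + subvoxel shift) to the phantom anatomy and requires
recovery within 0.25 voxel (translation), 10% (rotation angle) and 0.5
voxel (affine translation). Two numerical points are worth recording:

* The misaligned member of a phantom pair is *repainted analytically* at
  the transformed coordinates rather than resampled. Resampling would
  smooth the moving image along the motion direction and displace the NCC
  optimum away from the true pose — an artifact of fixture construction,
  not of registration.
* When registering baseline to CE, the NCC ceiling is well below 1 because
  the target genuinely contains contrast enhancement the baseline lacks;
  the suite therefore checks that the optimum reaches the metric value at
  the true pose, not an absolute threshold.

## VOI quantification

All regions are axis-aligned ellipsoids; a voxel belongs to a VOI iff its
center satisfies $\sum_i ((x_i - c_i)/a_i)^2 \le 1$ (center-point
membership, no partial-volume weighting — exactly testable and matching
common VOI tools). The tumor region set is derived deterministically:

* **Core**: concentric ellipsoid with half the tumor's semi-axes (one
  eighth of its volume).
* **Periphery**: four equal VOIs at $\pm x$, $\pm y$ offsets of 0.75 tumor
  semi-axes, each with 0.2 tumor semi-axes. The count (four, placed in the
  tumor outside the core) is prescribed; size and placement are not, so
  the 0.75/0.2 rule was chosen to guarantee, in tumor-normalized
  coordinates, containment ($0.75 + 0.2 \le 1$), core exclusion
  ($0.75 - 0.2 \ge 0.5$) and pairwise disjointness
  ($\sqrt 2\,\cdot 0.75 > 0.4$); all three are re-verified at run time.
  Periphery statistics pool the voxels of the four VOIs (primary); the
  mean-of-means alternative is available for sensitivity checks.

Relative blood volume normalizes tissue iodine by the arterial
concentration, $rBV(\%) = 100\, C_I / C_{I,aorta}$, which cancels
inter-animal variability in contrast delivery; it is scale-invariant under
global rescaling of the $C_I$ image by construction. The reported SD of an
rBV value uses the first-order ratio rule under an independence
assumption; it is for orientation only and enters no test.

Aggregation convention: scatter-plot-level data are summarized as mean ±
SD per animal, table-level summaries across animals as mean ± SEM
(`aggregate_quant()`).

## Dynamic stage: Patlak analysis under continuous infusion

The irreversible two-compartment model under continuous infusion gives

$$C_{tissue}(t) = \frac{K^{trans}}{60} \int_0^t C_{AIF}(\tau)\,d\tau +
rBV \cdot C_{AIF}(t),$$

with $K^{trans}$ in min$^{-1}$ ($/60$ converts to s$^{-1}$), and the Patlak
linearization

$$\frac{C_{tissue}(t)}{C_{AIF}(t)} = \frac{K^{trans}}{60}
\frac{\int_0^t C_{AIF}\,d\tau}{C_{AIF}(t)} + rBV,$$

so that ordinary least squares of $y = C_{tissue}/C_{AIF}$ on
$x = \int C_{AIF}/C_{AIF}$ over the 30–80 s window yields $K^{trans}$
(slope ×60, reported min$^{-1}$) and rBV (intercept ×100, reported %).
The no-back-flux assumption holds during continuous infusion, which is the
condition this package implements (bolus-injection deconvolution is out of
scope).

Numerical choices:

* The AIF integral uses the **cumulative trapezoid from $t=0$**, and the
  forward generator uses the *same rule*, so the forward → transform → fit
  round trip is exact to machine precision on noise-free data (verified
  over a 5×5 grid of $(K^{trans}, rBV)$ pairs at $10^{-6}$ relative). The
  trapezoid is also *exact* on the piecewise-linear ramp AIF, which is why
  a closed-form integral serves as an independent oracle in the tests.
* The AIF shape is a linear ramp (default 20 s) to a constant plateau
  (default 6 mg I/mL): the published time–concentration curves of the left
  ventricle show a constant level after an initial slope, but neither the
  plateau value nor the ramp time is stated, so both are explicit,
  configurable parameters rather than inferred constants.
* Fits run on **raw curves by default**; moving-average smoothing
  (`smooth_curve()`, default window 5 s, truncated at the edges) is
  available but opt-in, because smoothing the ratio variables biases the
  regression. Whether the original analysis fitted smoothed or raw curves
  is unstated.
* `patlak_transform()` refuses a non-positive AIF at any evaluated sample;
  windowed evaluation (the standard path) starts after the ramp, where the
  AIF is strictly positive.

### Planar projection geometry

DCE frames are fixed-angle parallel projections (sum along one axis ×
voxel size, units value·mm) of the time-varying 3D concentration map plus
the static anatomy. Rotation of the real gantry adds no testable content
and is omitted. Because projections are line integrals, an extracted ROI
mean carries a path length; for a homogeneous ellipsoidal organ the mean
chord along the projection axis is $V / A_{proj} = \tfrac43 a_z$
(`voi_effective_thickness()`), and dividing by it recovers absolute
concentration to within voxelization error (a few percent on the default
grids). Without that correction the extracted curve is proportional to the
true one, which Patlak's AIF-scaling invariance tolerates only if tissue
and AIF share the factor — a real limitation of planar DCE that the
generator reproduces, including the optional superimposition of an
overlapping organ onto the tumor projection (`overlap_labels`), which
biases the tumor curve upward at every time point.

## Statistical stage

`pearson_with_ci()` implements the Pearson coefficient with a two-sided
$t$-test on $n-2$ degrees of freedom and a Fisher-$z$ 95% CI (degenerating
to $[-1, 1]$ at $n = 3$); its coverage is property-tested at
$\rho = 0.7$, $n = 8$ over 2000 simulations. `compare_groups()` delegates
to `stats::aov`/`TukeyHSD`/`t.test` — the contract, enforced on balanced
toy designs, is agreement with the closed-form $F$ and pooled-variance $t$
formulas; the two-way design adds Bonferroni-adjusted cell-mean contrasts
using the pooled residual variance. `correlation_screen()` evaluates all
imaging-parameter × region × histology pairs joined on `tumor_id` and
applies **no multiplicity adjustment by default**, mirroring the original
reporting; Benjamini–Hochberg is available behind a flag. Tumors are
treated as independent observations (two tumors per animal in the emulated
design); whether the original correlations pooled tumors or animals is
unstated, and the tumor-level default is the generator's own convention.

## The synthetic world

The generator's defaults state one fixed working point rather than tunable
dials:

* Iodine-to-enhancement gain 50 HU per mg I/mL (calibration slope
  0.02 (mg I/mL)/HU), the SE working point used throughout the examples
  (tumor 1.55, muscle 0.72, aorta 6.2 mg I/mL — enhancement 77.5 HU in the
  tumor).
* DE pairs are constructed phenomenologically: unenhanced tissue satisfies
  $HE = 0.55\,LE$ exactly before noise, and iodinated organs receive an
  HE-only additive term proportional to $C_I$. No tabulated attenuation
  coefficients are simulated — the downstream pipeline only needs a signal
  that survives weighted subtraction, and this construction makes tissue
  cancellation an exact, testable invariant.
* Dynamic truth: tumor $K^{trans} = 0.24$ min$^{-1}$, $rBV = 11.6\%$;
  muscle $0.13$ min$^{-1}$, $12.2\%$; AIF plateau 6 mg I/mL after a 20 s
  ramp; 1 s sampling over 0–80 s.
* Noise is additive Gaussian in HU, independent per voxel and per volume
  (Poisson projection noise is out of scope); histology marginals default
  to the published 8-tumor group values with SDs reconstructed from the
  reported standard errors, and each histology variable is drawn with a
  controllable correlation against a supplied imaging parameter, then
  clipped to its physical range (clipping can shrink realized
  correlations when marginals push against the bounds — the generator
  does not correct for this).
* Every stochastic operation takes an explicit seed and restores the
  caller's RNG state; fixed seed implies bit-identical output, which is
  asserted in the tests.

What a green suite establishes: the pipeline inverts its own forward
models exactly, degrades gracefully under the stated noise, and its
statistics are calibrated. What it does not establish: accuracy on real
scanner data — no spectra, scatter, beam hardening, reconstruction
artifacts, motion, or anatomically realistic textures are simulated, and
the DE model is deliberately phenomenological.

## Known limitations

* Registration assumes equal voxel spacing of moving and fixed volumes and
  a mostly-overlapping field of view; deformable registration is out of
  scope.
* The planar DCE stage quantifies region-level curves, not voxelwise
  parametric maps, and inherits the superimposition bias of projection
  imaging discussed above.
* `read_nifti()`/`write_nifti()` support the subset of NIfTI-1 the package
  emits (uncompressed, 3D, float32/float64, scale slope/intercept honored
  on read); they are not a general NIfTI implementation.
* Group comparisons require complete cells (≥ 2 observations); unbalanced
  designs with empty cells are rejected rather than approximated.
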