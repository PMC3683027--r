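---
title: "Dynamic ventilation maps from 4D CT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic ventilation maps from 4D CT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungvent)
```

## The problem

During a breath the lung parenchyma expands and recruits air unevenly:
regional ventilation — the volume of air each small tissue region gains
between two points of the breathing cycle — is a sensitive functional
readout, and in emphysema models it becomes markedly more heterogeneous.
Dynamic (no-breath-hold) micro-CT of a mechanically ventilated rodent
captures the moving lung as a series of 3D volumes over one averaged
breathing cycle (11 phases here, ~150 µm isotropic voxels, tracheal pressure
cycling between ~0 and ~8 cmH2O). `lungvent` turns such a series into
voxel-level volume-change ("ventilation") maps and validates them against
the ventilator's own pressure–volume (PV) measurements.

The chain is: image preparation → non-rigid registration of every phase to
the lowest-inflation (end-expiration) frame → finite-element kinematics of
the resulting displacement fields → Hounsfield-calibrated air fractions →
kinematic and intensity-joint ventilation maps → PV loop, compliance,
heterogeneity, and landmark accuracy reports.

## Kinematics

Registration of source phase $t$ to the reference yields, per reference
voxel center $X$, a displacement $u(X)$ in mm under the pull-back
convention: $x(X) = X + u(X)$ is the corresponding position in the source
image, directly usable for resampling. The voxel centroids are taken as
nodes of a mesh of trilinear isoparametric 8-noded hexahedral elements
(a grid of $n_x n_y n_z$ voxels carries $(n_x{-}1)(n_y{-}1)(n_z{-}1)$
elements). Per element, the deformation gradient is

$$F \;=\; \sum_{a=1}^{8} x_a \otimes \frac{\partial N_a}{\partial X},
\qquad J = \det F,$$

with the shape-function gradients evaluated at the element centroid and
mapped through the (diagonal) reference-element Jacobian. One centroid
evaluation point is used rather than full Gauss quadrature: the resulting
field is piecewise linear, exact for affine motions (trilinear completeness,
verified to machine precision in the tests), and second-order accurate
otherwise. The full tensor $F$ is retained — not just $J$ — so the
volumetric/deviatoric split $\bar F = J^{-1/3} F$ is available for strain
analyses.

Element values become voxel maps by averaging over each voxel's incident
elements (up to 8). Interior voxels have a symmetric 8-element stencil and
inherit the $O(h^2)$ accuracy (halving the spacing reduces the maximum
error ~4x in the tests); the single outermost voxel layer has a one-sided
stencil and is first-order — irrelevant in practice because the lung never
touches the grid boundary. Elements with $J \le 0$ (non-physical folding)
are flagged, counted, excluded from summary statistics, and retained in the
maps.

The kinematic ventilation estimate is $rV = (J - 1)\,V_0$ per in-mask
voxel, with $V_0$ the reference voxel volume ($0.15^3\,$mm$^3$ = $3.375
\times 10^{-6}$ mL).

## Air fractions and the joint estimate

A lung voxel's CT number is, to good approximation, a linear blend of a
tissue value and an in-lung air value by its air fraction
$\beta = (HU_{tiss} - I)/(HU_{tiss} - HU_{air})$, clamped to $[0,1]$ for
noisy voxels. In-lung air reads well above the nominal −1000 HU (shading,
view aliasing, beam hardening), so the calibration pair is estimated per
group from the pooled highest-inflation histogram: $HU_{tiss}$ is the
tissue mode (1-HU bins, 10-HU smoothing); $HU_{air}$ is $\mu - 2\sigma$ of
a Gaussian fitted to the isolated lung peak — a log-quadratic fit over the
half-maximum region, which is a least-squares Gaussian fit without
iterative fragility. Configured defaults (−781, −122 HU) correspond to a
healthy control group.

A purely kinematic map can mislead: a territory distal to a collapsed
airway deforms with its surroundings yet admits no air. The joint estimate
therefore combines motion and density change:

$$rV_{joint} = V_0\,\bigl(J\,\beta_f(T(\phi)) - \beta_r(\phi)\bigr),$$

where $\beta_r$ is the reference air fraction and $\beta_f$ is the floating
image's air fraction sampled at the warped location. If local tissue volume
is conserved, $(1-\beta_f)J = (1-\beta_r)$, and the joint and kinematic
estimates coincide exactly; in a collapsed region the joint estimate
correctly reports $\beta\,(J-1)V_0 < (J-1)V_0$. The floating intensity is
sampled with tricubic (Catmull–Rom) interpolation: the sampled value enters
the estimate quantitatively, and trilinear interpolation error at vessel
and boundary interfaces would otherwise dominate the joint–kinematic
residual.

Heterogeneity is summarized as the coefficient of variation (population
SD/mean) of the map over unflagged in-mask voxels.

## Image preparation (levels A–E)

Direct registration of raw frames is poor: intensity changes with inflation
and the nearly static ribcage anchors the warp at the lung boundary. The
graded preparation pipeline is: A — nothing; B — bone replaced with
tissue-statistics noise; C — lung mask (26-connected region growing from a
seed below a threshold, then morphological closing) and background
saturation; D — C preceded by Gaussian filtering (radius 1, read as
$\sigma = 1$ voxel, 3$\sigma$ truncation, edge-renormalized so constants
are preserved); E — D followed by histogram equalization inside the mask.
The ablation utility re-registers one pair under all five levels and
reports landmark TRE per level; on phantoms with bright static structures,
level E is at least as accurate as level A.

Two details matter numerically and were deliberate choices:

* **Saturation level.** The background is saturated at the *in-mask
  maximum* (the ceiling of the lung's own intensity range, as when a binary
  mask is added to a display-windowed image), not at the global (bone)
  maximum. With a bone-level ceiling the mean-squared metric is dominated
  by ~1800-HU steps at the two images' independently segmented, voxel-
  quantized boundaries, and registration becomes hostage to segmentation
  noise.
* **Fixed equalization range.** Equalization maps the in-mask CDF onto a
  fixed output range (0–1000) with the outside at the ceiling. Mapping each
  image to its own min/max instead makes the background level drift with
  inflation (the inflated lung is darker), introducing a systematic
  intensity offset between phases that the optimizer "explains" with a
  spurious contraction.
* **Default mask threshold.** The histogram valley between the two lowest
  substantial intensity modes (parenchyma vs soft tissue). Modes are judged
  by mass within ±25 HU (≥2% of all voxels), not bin height, so a spread
  parenchymal mode is not drowned out by a near-delta background spike in
  clean synthetic images; plain Otsu is the fallback.

## Registration

A two-stage estimate per source phase: an affine stage (4×4×4 subsampling,
30 iterations) then a cubic B-spline free-form deformation (control-point
spacing 10 voxels, no image subsampling, 30 iterations), both minimizing
mean squared intensity error. The affine parameters are optimized by
Levenberg–Marquardt (12 parameters, exact normal equations); the control
points by gradient descent with a backtracking line search — the objective
is non-increasing over accepted iterations by construction, and the first
step is sized to move no voxel more than half a voxel.

The metric is evaluated over the target lung mask dilated by 3 voxels.
Prepared images are ~75% uniform saturated background; over the full grid
the MSE is degenerate there (a collapse transform that maps everything into
the background can outscore alignment), while the dilated mask keeps the
informative boundary step and interior texture.

The smoothness penalty is the squared Frobenius norm of control-point
second differences — a bending-energy surrogate — normalized by the
metric-region intensity variance divided by the squared control spacing, so
the default weight 0.001 is dimensionless and effective across intensity
scales. Raw mm-scale penalties are numerically invisible against HU²-scale
data terms. The weight is a default, not a calibrated constant.

Iteration counts are deliberately left at 30: on phantom studies the
objective keeps creeping down past that point while the endpoint error
*rises* — the surplus iterations fit noise. Two further facts, measured on
phantoms and worth knowing:

* With 4×4×4 metric subsampling on small (≤64³) test grids the recovered
  scale is biased by ~1%: too few boundary samples. The recovery tests use
  2×2×2 on such grids; full-size images are unaffected in proportion.
* Registration accuracy and Jacobian accuracy are different currencies. A
  tissue-conserving inflation carries an intensity gradient (higher local
  $J$ = darker parenchyma) that a mean-squared metric can partially explain
  by a slightly contracted warp. The resulting ~0.4-voxel radial bias is
  far inside the landmark acceptance bound (mean TRE ≈ 0.1–0.5 voxel
  against a √3 ≈ 1.73-voxel bound) yet shifts the mask-summed $J$ — and
  hence total-volume curves — by ~10%. This is the density/motion confound
  that motivates the joint estimate, which recovers roughly half of the
  deficit. For end-to-end map validation the pipeline therefore supports
  (and the acceptance analysis uses) externally supplied displacement
  fields through the import path, mirroring a workflow in which
  registration is an exchangeable component; built-in-registration results
  are reported alongside.

## The phantom test bed

No public data accompany this class of experiment, so the package carries a
first-class phantom module: an ellipsoidal lung with a parenchymal air
fraction (default $\beta_r = 0.5$ at end expiration), an embedded vessel
tree (tissue HU; branch points double as landmarks), a central air-filled
airway, rib-like bone arcs, band-limited parenchymal texture, and Gaussian
noise (default SD 20 HU). Intensity follows the same linear air-fraction
mixture the ventilation module inverts — with noise present this is not an
inverse crime, and noise-free variants are used only where an exact
identity is being verified.

Deformations are closed-form fields (affine, radial inflation with a
Gaussian envelope, per-axis sinusoids, and compositions) with exact
Jacobians, so every kinematic quantity has an oracle. Deformed "source"
images are built by evaluating the analytic model at the numerically
inverted field (fixed-point iteration to 1e-10), under either a passive
(pure-warp) or a tissue-conserving intensity model
($\beta_f = 1 - (1-\beta_r)/J$); a collapsed-region option holds $\beta$
fixed where an airway is meant to be closed, making kinematic and joint
maps disagree there by construction.

Two generator properties are load-bearing:

* **Band-limited edges and texture.** All interfaces are smoothed over 2
  voxels — the effective reconstruction point-spread width — because a
  reconstructed CT volume is band-limited and a sharper synthetic edge is
  aliased on the sampling grid (no interpolant can resolve it, which
  corrupts any quantity that samples intensities off-grid). The parenchymal
  texture (60 random-phase cosines, wavelengths 4–12 voxels, SD 0.06 in
  air-fraction units ≈ 40 HU) stands in for unresolved vasculature and
  acinar structure: real parenchyma is not featureless, and without texture
  histogram equalization amplifies pure noise into full-range clutter that
  destroys registration correspondence.
* **Exact study bookkeeping.** An 11-phase study pairs a simulated
  ventilator loop (compliance from a peak parenchymal volume ratio of 1.6 —
  a rat tidal breath of ~2.6 mL on an FRC of ~4 mL — peak pressure 8
  cmH2O, 400/600 ms inhale/exhale, hysteresis 15% of tidal volume) with
  per-phase fields composed of a mean-zero sinusoidal perturbation and a
  uniform inflation whose factor is solved so the mask-summed analytic
  Jacobian reproduces the trace volume exactly. Map-derived PV curves can
  therefore be compared to the trace without a discretization fudge.

What passing phantom tests do *not* show: performance under real
reconstruction artifacts (shading, streaks, beam hardening), cardiac
motion, lobar sliding, or observer landmark variability. The phantom's
geometry is far simpler than a real lung, and its texture statistics are
stationary where real parenchyma is not.

## Validation

Landmark TRE is the Euclidean displacement, in voxel lengths, between a
landmark's position in the target and in the warped image (or between
ground-truth and estimated fields at the landmark, for phantoms). A
landmark is *misregistered* when it is off by more than one slice in z
and/or farther in-plane than the largest in-plane nearest-neighbor distance
(√2 voxels; strict inequality with a 1e-9 tolerance, so an exact diagonal
is not flagged). Any displacement within the rule is then within the
largest 3D nearest-neighbor distance (√3 ≈ 1.73 voxels) — the property the
tests assert; the printed 1.41/1.73 are these irrational bounds rounded to
two decimals. TRE summaries use the population SD. A click-error utility
re-identifies landmarks on a radius-1-blurred copy of the target by local
normalized cross-correlation, characterizing observer error as a report,
not a gate.

PV loops are assembled by summing each phase's ventilation map over the
mask and pairing totals with the trace's pressures by acquisition time;
the first (target) phase has volume 0 by construction. Compliance is the
OLS slope of volume on pressure over the inhale limb by default (ventilator
volumes in such experiments were historically inhale-only; exhale and
both-limb options exist, and a study too short for two inhale samples falls
back to the full loop). Hysteresis is the shoelace area of the closed loop,
positive when the exhale limb lies above the inhale limb in volume — the
physiological orientation; crossing limbs trigger a warning and a signed
area.

## Numerical choices and degenerate inputs

* Voxel indices are 0-based in every user-facing interface; world
  position = origin + index × spacing (mm); displacement fields are stored
  in mm so a spacing change cannot silently rescale kinematics.
* Anisotropic input volumes are rejected unless an explicit spacing
  override is given.
* Warping uses trilinear interpolation with a background fill for
  out-of-domain samples; quantitative intensity sampling (air fractions)
  uses tricubic.
* NIfTI files are written as NIfTI-2 (64-bit header fields) so spacing
  metadata round-trips exactly; MetaImage and multi-page TIFF stacks are
  the other supported formats.
* Degenerate cases error early and descriptively: non-3D input, seeds
  outside the threshold region, empty masks, constant images under
  equalization (warning + no-op), control grids larger than the image,
  non-monotone trace times, duplicate landmark ids, zero-mean maps under
  CoV.

## Problem sizes

The test suite and the acceptance analysis run phantom studies at 32³–64³
with 3–11 phases — large enough that the lung spans ~25–50 voxels and every
discretization claim (exactness, convergence order, conservation) is
measurable, while a full run stays in the minutes range on one CPU. The
same code paths handle full-size (512³) series; only memory and patience
scale.
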