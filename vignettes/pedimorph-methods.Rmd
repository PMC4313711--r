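---
title: "PediMorph: models, measurement conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PediMorph: models, measurement conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind the
package: what the synthetic phantoms emulate and what they do not, how
each measurement is defined where the field's verbal conventions are
ambiguous, and which tolerances the test suite enforces at which problem
sizes.

## 1. The head phantom

A subject is modelled as nested, origin-centred, axis-aligned ellipsoids
(all lengths in mm, world coordinates RAS with the head centre at the
origin):

* **scalp** with semi-axes (a_s, b_s, c_s) — default 76 x 93 x 106, an
  adolescent-sized head;
* **inner skull** = scalp minus a constant `skullThickness` (default
  6 mm) on each semi-axis; the shell between the two stands for skull
  plus scalp soft tissue and is rendered at the GM mean intensity;
* **brain** ellipsoid (default 61 x 73 x 86) separated from the inner
  skull by a `csfGap` (default 4 mm) of CSF-intensity subarachnoid
  space;
* **white matter** as the brain scaled by `wmFraction` (default 0.77),
  and inside it an optional central CSF ellipsoid standing for the
  ventricular and deep CSF space.

Intensities follow the T1 ordering CSF < GM < WM (defaults 30/70/110
arbitrary units) with additive Gaussian noise (default sd 5) behind a
single seed. The six landmarks are placed analytically: preauricular
points at (±a_s, 0, 0), nasion/inion on the scalp surface at the
configured elevation above the AC–PC plane (default 0, making all six
landmarks coplanar so the two head-volume cut planes coincide and the
half-ellipsoid closed form applies), and AC/PC on the
anterior–posterior axis (defaults ±13.2, i.e. an AC–PC distance of
26.4 mm).

**Partial-volume ground truth.** Each voxel is supersampled with s³
points (default s = 3) against the analytic surfaces. The subsample
offsets use a staggered (rotated-grid) stratification: along each axis
the s³ points take s³ distinct offsets, so the boundary inside-fraction
ramps in s³ levels rather than s, which is what makes sub-voxel surface
localisation possible at 2 mm voxels. Offsets are shared across surfaces
within a pass, so counted memberships are exactly nested and the PVE
identity GM + WM + CSF = 1 holds exactly inside the brain mask.

The stored PVE maps are *within-brain fractions*: at a boundary voxel
the compartment fractions are divided by the voxel's brain fraction,
exactly the convention a posterior-probability segmentation produces.
Summed over the brain mask they telescope to the analytic compartment
volumes up to the voxel-count error of the mask itself (≈0.1 % at 2 mm).

**Compartment masks** carry a deliberately widened boundary ramp: the
raw fractions are smoothed twice with the separable [1,2,1]/4 kernel.
The smoothing is symmetric, so the 0.5 level set stays on the analytic
surface for locally planar boundaries, while the ramp becomes wide
enough (≈4 voxels) to be represented faithfully by trilinear
interpolation. Without it, the one-voxel-wide partial-volume ramp makes
the interpolated 0.5-crossing biased inward by up to ≈0.09 voxel per
side. The residual errors at 2 mm voxels are a curvature-induced inward
shift of order κσ² (≈0.1 mm per side on the brain) plus interpolation
kinks; measured worst-case distance error over simulated cohorts is
≈0.4 mm at 2 mm spacing and <0.1 mm at 1 mm.

**What the phantoms do not emulate:** cortical folding, bias fields,
scanner artefacts, tissue-intensity inhomogeneity, and realistic
ventricle anatomy. Passing tests therefore show the *measurement
machinery* is correct to stated tolerances, not that the segmentation
would reach those tolerances on clinical scans.

## 2. The cohort simulator

`defaultGrowthModel()` carries the seven distance measures plus total GM
and WM volume for two groups (presets CN/US), ages 8–16. Group effect
*directions* mirror the qualitative contrasts reported for
Chinese-vs-U.S. pediatric cohorts — the second group has longer
heads/brains, the first wider and taller ones; total GM follows an
inverted U peaking earlier for the second group (ages 10 vs 12); WM
rises linearly — but the *magnitudes* are synthetic choices (linear
slopes under 1 mm/y, residual sds of 1.5–2.5 mm on distances and 2–3 %
on volumes), picked once as order-of-magnitude plausible for this age
range. No claim is made of reproducing real effect sizes, which the
source tables do not print.

Per subject, the seven drawn distances determine the six semi-axes and
the AC/PC offsets (AC and PC symmetric about the origin); the drawn GM
volume then fixes `wmFraction`, and the drawn WM volume fixes the deep
CSF volume. Brain, intracranial and head volumes are consequently
*derived* quantities — with three semi-axes already pinned by distances
the system would otherwise be overdetermined — and are recorded as
per-subject analytic truth rather than being independently drawable.
A side effect is that the deep-CSF compartment absorbs the volume
bookkeeping and is far larger than anatomical ventricles; it is a
bookkeeping compartment, not an anatomical claim. Default trajectory
parameters were sized so that the nested-ellipsoid constraints hold
with ≥4.5 σ margins across the reference cohort (282 subjects).

The default demographic table is the published one-year binning of the
two cohorts (133 + 149 subjects including per-bin male counts); the
two-year regrouping uses the bins {8}, {9–10}, {11–12}, {13–14},
{15–16}.

## 3. Measurement conventions

Several verbal definitions admit more than one reading; the package
fixes them as follows (all configurable where noted):

* **Line measures** sample the mask along the line at 0.1 mm steps
  (configurable) with trilinear interpolation and take the first/last
  sample ≥ 0.5. Brain length runs along the AC–PC line itself; brain
  width along the left–right normal **through the AC–PC midpoint** (the
  text does not say where along AC–PC the normal sits; the midpoint is
  the symmetric choice — pass a frame built at AC or PC to move it);
  brain height from PC superiorly to the last in-mask sample.
* **Head length and width** are Euclidean landmark distances
  (nasion–inion, preauricular–preauricular), not line–mask
  intersections.
* **Superior orientation** of the frame is fixed by scalp-mask
  asymmetry (the side with the greater extent above the AC–PC plane is
  "up"); without a mask, by the right-handed cross product. When the
  mask flips the superior axis, the left–right axis is flipped with it
  to keep the triad right-handed; no distance measure depends on these
  signs.
* **Head volume** counts scalp-mask voxel *centres* on the superior
  side of **both** reference planes (the roof-shaped wedge over the
  preauricular axis). Counting "above either plane" would double-count
  the inter-plane wedge; both rules are selectable. No partial-voxel
  plane clipping is attempted, consistent with the voxel-count style of
  the other volumes.
* **PVE volumes** are Σ(PVE)·voxel-volume over the selection. The
  verbal formula "sum of PVE values multiplied by the number of voxels"
  is dimensionally impossible if read literally and is implemented as
  the sum times the voxel volume.
* **Majority-vote ties** resolve to the smallest label id —
  deterministic and order-independent; voxels whose majority is
  background stay background and are reported in the fusion QC table.

## 4. Segmentation

Tissue classification is an intensity-only k = 3 Gaussian mixture fitted
by EM within a supplied brain mask (brain extraction is out of scope;
masks are inputs). Initialisation is a deterministic quantile split of
the masked intensities refined by ten Lloyd (k-means) iterations — the
refinement matters when one class is small and well separated (CSF at
low noise), where the raw quantile split can start two components on the
same mode and EM cannot subsequently separate them. An optional seeded
jitter perturbs the initial means. Component sds are floored at 10⁻⁴ of
the intensity range; hitting the floor is flagged. Components map to
tissues by ascending mean (CSF < GM < WM under T1 contrast). Posteriors
give soft PVE maps; voxels where all component densities underflow
(possible with near-point-mass components on noise-free data) fall back
to nearest-mean assignment.

Unlike full segmentation tools there is no Markov-random-field spatial
regularisation and no bias-field model: on smooth phantom compartments
intensity-only EM suffices (mean absolute PVE error ≈0.015 at noise
sd 5 on the default phantom), but mixture means are biased on data whose
boundary voxels are true mixtures, which is visible as a few-percent
bias in EM-derived tissue volumes on *noise-free* phantoms (the
worst case for this model). The end-to-end pipeline invariant — volumes
within 1 % of truth — therefore holds on the ground-truth-PVE path, and
the segmentation path is validated by its own tolerances (mixture means
within 1 unit; PVE MAE ≤ 0.1).

## 5. Atlas registration and fusion

Synthetic "atlas heads" are perturbed copies of the template phantom;
registration is least-squares affine on point pairs. Real multi-atlas
pipelines use intensity-based nonlinear registration; affine is the
appropriate model class for these ellipsoidal fixtures, and the fusion
logic (nearest-neighbour label pull-back, per-voxel plurality vote) is
identical either way. Note that the six anatomical landmarks are exactly
coplanar whenever nasion and inion sit on the AC–PC plane, so
registration uses a seventh derived point — the scalp vertex above PC
(`registrationPoints()`), giving a well-conditioned 3D fit.

## 6. Statistics

The MANOVA/GLM layer is implemented directly (not delegated): Type III
hypothesis SSCP matrices via general linear hypotheses on coefficient
blocks under sum-to-zero coding — the convention that reproduces
classic statistical-package df bookkeeping on unbalanced cohorts — with
the error SSCP from full-model residuals and vₑ = N − rank(X). Wilks' Λ
is transformed to Rao's approximate F; the denominator df is reported
rounded to the nearest integer (matching the published "F(16, 816)"
style) while the exact fractional value is used for p-values. For s = 1
effects (p·q ≤ 2) the transformation is exact, and for p = 1 it reduces
algebraically to the univariate F — both are tested, as is agreement
with `car::Manova`/`car::Anova` as an independent reference.

Peak ages come from an OLS quadratic in age centred at 12 years (for
conditioning), reported only when the curve is concave with an interior
vertex; confidence intervals are subject-resampling bootstraps
(percentile, default 500 replicates) rather than delta-method — robust
to the small per-bin counts typical here. Degenerate bootstrap resamples
(rank-deficient or convex) are dropped. For 50-region scans
Benjamini–Hochberg adjusted p-values are emitted alongside raw ones.

Sex enters the factorial models only when the design formula requests
it, mirroring the analysis convention of controlling for gender in the
volumetric but not the morphometric comparisons.

## 7. Problem sizes and tolerances in the tests

* Phantom-geometry acceptance: 10 simulated subjects at 2 mm voxels
  (grids ≈ 80 x 98 x 112); all seven distances within 0.5 mm, all
  compartment volumes and the plane-cut head volume within 1 % of the
  closed forms.
* Sub-voxel properties (0.5 mm at 1 mm spacing, tissue volumes within
  1 %) run on a compact 1 mm phantom.
* Segmentation: 10⁵-sample mixture recovery within 1 intensity unit;
  phantom PVE MAE ≤ 0.1 at noise sd 5.
* Fusion: exhaustive 27-pattern vote oracle; registration recovery to
  1e-8 on exact point pairs.
* Calibration: MANOVA type-I error within the 95 % binomial envelope
  over 2000 null simulations (n = 60, p = 3); peak ages 13 vs 11
  recovered within bootstrap CIs at n = 40/group, residual 5 % of peak,
  500 replicates.

## 8. Known limitations

* Ellipsoidal geometry: no gyrification, no asymmetry; regional
  parcels are angular sectors, not anatomy.
* The EM segmenter's boundary bias (Section 4) propagates into
  EM-derived regional volumes; trajectory *shapes* survive (measured GM
  correlates >0.9 with truth in the pipeline tests) but absolute
  EM-derived volumes should not be read as unbiased.
* Landmark placement is analytic, so landmark-identification error —
  a real source of variance in manual morphometry — is not modelled.
* The statistics layer assumes complete cases and two groups for the
  peak-age contrast.
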