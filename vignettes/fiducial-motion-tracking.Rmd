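---
title: "Estimating intrafraction tumor motion from stereo kV fiducial tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating intrafraction tumor motion from stereo kV fiducial tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fidtrack)
```

## The problem

During stereotactic body radiotherapy (SBRT) of liver tumors, respiration
moves the target by up to ~25 mm under free breathing, dominantly along the
superior–inferior (SI) axis. Liver tumors are nearly invisible on kV X-ray
images, so 3–4 radio-opaque gold fiducials are implanted near the tumor as
surrogates. A robotic radiosurgery system images the patient with two fixed
oblique kV sources every ~40 s over a ~38 min fraction; each acquisition
yields one orthogonal image pair. `fidtrack` turns those image pairs into a
per-frame rigid motion estimate — three translations and three rotations —
plus residual-error statistics that quantify how much of the observed
fiducial displacement a rigid model explains.

The pipeline has four stages, each usable on its own:

1. **Segmentation** — mean filter, binarization, 8-connected blob
   extraction with an area filter, blob centroids, and pairing of
   detections across the two views (`detect_markers()`, `pair_views()`).
2. **3D reconstruction** — back-projection of each paired detection under a
   parallel-ray model (`reconstruct_set()`).
3. **Rigid registration** — each frame's marker set is registered to the
   reference frame (the acquisition near the beginning of treatment) by a
   closed-form unit-quaternion fit inside an ICP loop (`icp_register()`),
   next to a translation-only baseline (`translation_only_fit()`).
4. **Motion statistics** — per-fraction peak-to-peak motion ranges, the 3D
   range, and the paired comparison of residuals with and without
   rotational correction (`motion_range()`, `summarize_cohort()`,
   `residual_comparison()`).

A synthetic fraction simulator (`simulate_fraction()`) generates fully
ground-truthed inputs — marker configurations obeying the clinical
implantation constraints, breathing-driven rigid motion, per-marker
deformation jitter, stereo projections and optionally rendered detector
images — so every stage can be validated end to end.

## Geometry and reconstruction

Patient axes are x = left–right (LR), y = anterior–posterior (AP),
z = superior–inferior (SI). Under the parallel-ray assumption, a marker at
patient position $(x, y, z)$ projects onto detectors A and B at
$(u_a, v_a)$ and $(u_b, v_b)$ with $v_a = v_b$: both views share the SI
coordinate. Reconstruction is a single z-axis rotation by the mounting
angle $\theta$ between the image and patient frames:

$$
\begin{pmatrix} x \\ y \\ z \end{pmatrix} =
\begin{pmatrix}
\cos\theta & -\sin\theta & 0 \\
\sin\theta & \cos\theta & 0 \\
0 & 0 & 1
\end{pmatrix}
\begin{pmatrix} u_a \\ u_b \\ (v_a + v_b)/2 \end{pmatrix}
$$

The two $v$ coordinates are averaged even when segmentation noise makes
them differ. `project_point()` applies the transpose rotation and is the
exact algebraic inverse; the round trip is exact to floating round-off for
any $\theta$.

Parameters: `theta_deg` defaults to 45° (oblique sources; any value and
either sign is supported — the in-plane rotation direction is an
installation convention), `pixel_spacing_mm` defaults to 0.39 mm for a
1024×1024 flat panel and is purely a scale factor. Divergent-beam
(point-source) geometry is deliberately not modelled.

## Rigid registration

With reference set $X = \{x_i\}$ and target set $Y = \{y_i\}$ in
correspondence, the fit minimizes the mean squared residual

$$
\Sigma^2 = \frac{1}{n}\sum_{i=1}^n \lVert x_i - (R\,y_i + T)\rVert^2
$$

over proper rotations $R$ and translations $T$. The rotation is obtained in
closed form by the unit-quaternion method: the cross-covariance
$\Sigma_{yx} = \frac1n \sum_i y_i x_i^T - \mu_y \mu_x^T$ is folded into a
symmetric 4×4 matrix (`build_Q()`) whose maximum-eigenvalue unit
eigenvector is the optimal quaternion; then $T = \mu_x - R\,\mu_y$.

**Why quaternions rather than SVD.** The unconstrained SVD (Kabsch)
solution $V U^T$ may be an improper orthogonal matrix — a reflection,
$\det = -1$. With only three markers this is not an edge case: three
centered points always span a rank-2 cross-covariance, so the sign of the
uncorrected SVD determinant is decided by the arbitrary orientation of the
null singular direction and comes out negative on roughly *half* of all
trials. The quaternion construction cannot produce a reflection: the
rotation matrix is rebuilt from a unit quaternion, so $\det R = +1$ always,
coplanar sets included. `svd_fit()` is provided as a diagnostic/comparison
fit (with the standard determinant sign fix available); the pipeline never
uses it.

**ICP.** Correspondence is established by the nearest-neighbour rule (ties
broken toward the lowest reference index), then the closed-form fit is
recomputed, iterating until the RMS residual decreases by less than the
threshold (default 0.001 mm) between successive iterations, with the
correspondence stable. The threshold is applied to the *change* in RMS
residual: under deformation noise the residual itself has no reason to fall
below 0.001 mm, but its change does at convergence. With markers >20 mm
apart and motion ≤20 mm, matching from an identity start is unambiguous and
convergence takes 1–3 iterations; `max_iter = 50` is a safety cap that
flags rather than errors. With labelled markers (`labelled = TRUE`) the
loop reduces to a single closed-form fit; the unlabelled ICP mode is the
default since real detections carry no identities. Exactly collinear
configurations leave the rotation about that axis unobservable; the solver
returns the minimum-angle representative and warns when the leading
eigenvalue of the 4×4 matrix is numerically repeated.

Quaternions are scalar-first `(q0, q1, q2, q3)`, reported with the
canonical sign `q0 >= 0` (q and −q encode the same rotation).

## Motion quantities

Rotations are reported as extrinsic fixed-axes x-y-z Euler angles,
$R = R_z(\theta_z) R_y(\theta_y) R_x(\theta_x)$, in degrees about the
LR/AP/SI axes. The convention matters little at the magnitudes seen here
(≤ ~10°, where all conventions agree to first order) and gimbal lock is
canonicalized with $\theta_x = 0$. Translations in the motion trace are the
displacement of the reference marker centroid under the fitted transform —
with the default rotation center this isolates the breathing translation
from the rotation.

Per fraction, `motion_range()` reports each component's peak-to-peak range
and combines the three translational ranges as
$\Delta d = \sqrt{\Delta x^2 + \Delta y^2 + \Delta z^2}$. Across a cohort,
`summarize_cohort()` averages *per-fraction* ranges (sample SD, n−1
denominator); $\Delta d$ is computed per fraction and then averaged, not
recomputed from cohort-mean axis ranges — the two differ substantially and
only the former matches how per-case ranges combine.

`residual_comparison()` pools all frames and compares the mean absolute
LR/AP/SI residual components and the mean 3D residual magnitude between the
translation-only and full rigid fits, with a two-sided paired t-test per
quantity (`paired_t_test()`, closed form; a constant nonzero difference is
reported as $t = \pm\infty$, $p = 0$ and flagged, rather than erroring).
One subtlety: the fit minimizes mean *squared* residual, so the rigid model
is guaranteed never to lose to the translation-only model in per-frame RMS
(`res_rms_*` columns) — but the mean-of-norms tables can show rare
individual frames going the other way. Formatted tables print p-values
below 0.001 as "< 0.001"; exact values stay in the JSON.

## The synthetic fraction generator

The generator exists to provide ground truth at study-like conditions, not
to imitate any particular patient:

- **Markers**: 3 or 4 positions rejection-sampled uniformly in a ±30 mm box
  until every pairwise distance exceeds 20 mm and every triple angle
  exceeds 15° — the clinical implantation constraints.
- **Motion**: sinusoid plus optional linear drift per component,
  amplitudes (1.5, 2.8, 8.0) mm LR/AP/SI and (2, 2.5, 2)° about LR/AP/SI,
  period 4 s, rotations about the marker centroid, first frame normalized
  to the identity (it is the reference). These defaults place simulated
  per-fraction ranges in the regime reported for liver SBRT cohorts
  (~3/5.5/16 mm and a few degrees); they are scenario defaults, not claims
  about any dataset. Sinusoids are used because their ground-truth ranges
  are analytic (peak-to-peak = 2×amplitude).
- **Sampling**: 57 frames 40 s apart (~38 min). Since 40 s is a multiple of
  the 4 s period, strictly periodic sampling would hit the same breathing
  phase every frame; real imaging is not phase-locked, so by default each
  frame's phase is dithered uniformly over one period, making frames sample
  random breathing phases. Disable `phase_jitter` for analytic range
  checks.
- **Deformation**: independent isotropic Gaussian per-marker jitter
  (default SD 0.5 mm per axis), the non-rigid component that a rigid model
  cannot capture. This is what makes the rigid-vs-translation-only residual
  comparison non-trivial.
- **Images**: markers render as isotropic Gaussian blobs (SD 1.5 px, peak
  contrast 0.6 over a 0.1 background) with sub-pixel centers, optional
  pixel noise, low-frequency clutter and single-pixel specks. Real
  radiographs show elongated cylindrical seeds whose projected shape
  changes with angle, overlapping anatomy, and scatter — none of which is
  modelled, so passing image-path tests demonstrates the pipeline
  machinery, not clinical segmentation robustness.

Everything is a pure function of (inputs, seed): identical seeds give
bitwise-identical fractions.

Note on measured ranges: per-frame rotation estimates carry noise of order
(deformation SD)/(marker spread) ≈ 1°, so cohort *rotation ranges* measured
from tracked traces exceed the generating 2×amplitude noticeably; this
mirrors real range statistics, which also include estimation noise.

## Numerical and design choices

- **Segmentation order**: mean filter *before* thresholding
  (denoise-then-threshold); thresholding first would make the filter
  re-grow blobs and bias centroids.
- **Threshold default**: `detect_markers()` uses a half-max rule (midpoint
  of the median and maximum intensity). Otsu — the usual automatic choice,
  and still the `binarize()` default — assumes the foreground occupies an
  appreciable histogram mass; fiducials cover ~25 of 10^6 pixels, where
  Otsu's criterion can land inside the background noise and produce
  hundreds of false blobs. Both rules and a manual threshold are exposed.
- **Blob filter**: 8-connected components, area between 4 px (rejects
  noise specks) and 400 px (rejects large bright structures such as bone
  shadows). Centroids are unweighted means of member pixels;
  intensity-weighted centroids are available.
- **View pairing**: exact minimum-cost assignment on $|v_a - v_b|$ by
  permutation enumeration (detection counts are 3–4; exact up to 7 per
  view), pairs accepted within a 2 mm tolerance by default.
- **Eigen-solver**: dense symmetric 4×4 eigendecomposition
  (`eigen(symmetric = TRUE)`); a numerically repeated leading eigenvalue
  logs a degeneracy warning and returns an arbitrary leading eigenvector.
- **Serialization**: CSV floats carry 9 significant digits; config/result
  JSON carries 17 (exact doubles), so identical config + seed reruns are
  byte-identical.

## Problem sizes used in validation

The test-suite and acceptance checks run at desk scale: 10,000 random
points for the projection round trip; 500 random 3–6 marker instances
against an independent numerical minimizer (Rodrigues-parameterized BFGS
from 10 structured + 2 random starts); 360 coplanar 3-marker reflection
trials; single 57-frame fractions for exact-recovery, ICP-iteration and
image-path checks; and a 12-fraction cohort (684 frames) for the residual
comparison. These sizes make every check rerun in minutes while keeping
the Monte-Carlo assertions well inside their tolerances.

## Known limitations

- Parallel-ray geometry: no source–axis distance, detector tilt, or
  magnification; real systems are divergent-beam.
- Rigid motion only: deformation enters as noise, not as a model; no
  robust/trimmed ICP, no similarity transforms.
- The simulator's breathing is a stationary sinusoid (plus linear drift):
  no hysteresis, baseline shifts, or irregular breathing.
- Registration to a single reference frame (frame-to-frame chaining is
  available via `warm_start`, but drift analysis is out of scope).
- Segmentation is threshold-based; template matching and learning-based
  detection are out of scope.

## A worked example

```{r example, eval = FALSE}
library(fidtrack)

cfg <- simulation_config(n_frames = 57, seed = 1)
sim <- simulate_fraction(cfg)
trace <- track_fraction(sim)
motion_range(trace)

traces <- lapply(1:12, function(s) {
  track_fraction(simulate_fraction(simulation_config(n_frames = 57,
                                                     seed = s)))
})
summarize_cohort(traces)
cat(format_residual_table(residual_comparison(traces)), sep = "\n")
```
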