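---
title: "Contact kinematics of fixed-bearing UKA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact kinematics of fixed-bearing UKA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, conventions and numerical choices
behind `ukacontact`. The package analyzes where the femoral component of
a fixed-bearing medial unicompartmental knee arthroplasty (UKA)
articulates on the polyethylene (PE) insert during functional
activities, using 6-DOF component poses recovered from dual-view
fluoroscopic silhouettes, and compares the resulting contact statistics
against in vitro wear-region reference centers.

## Coordinate conventions

All component frames use a right-knee convention: x anterior(+),
y medial(+), z proximal(+), in mm. Left-knee data are mirrored across
the sagittal plane first (`mirror_left_to_right()`), which preserves
medial(+) as medial(+) and keeps the signs of adduction and internal
rotation anatomically meaningful; the operation is an involution and is
covered by conjugation tests. The convention is stamped into every CSV
header the pipeline writes, because sign-flip mistakes are the dominant
failure mode in this kind of analysis.

Poses are parameterized for optimization and noise injection as
intrinsic Z–X–Y Euler angles (degrees) plus a translation (mm). The
middle (X) angle is the gimbal-critical one; all phantom motion keeps it
far from ±90°.

## The synthetic phantom

No patient imaging or manufacturer CAD is available, so the package
ships a parametric phantom that preserves the properties the analysis
relies on, not the proprietary shapes.

* **Femoral condyle** (`make_femoral_component`): a torus section — a
  coronal circular arc (radius 11 mm by default) swept along a sagittal
  circular arc (24 mm) — closed into a watertight solid. This preserves
  the low-congruence, effectively single-point contact of the emulated
  design, and a torus has a useful exact property: rotation about its
  (medial–lateral) axis leaves the surface invariant, so the lowest
  articular point stays directly below the arc center at any flexion
  angle. An `arc_offset` parameter (default −25°, i.e. the arc biased
  posteriorly, mimicking the posterior extension of real condyles) keeps
  the contact on the articular band up to the ~100° flexion reached in
  the lunge.
* **PE insert** (`make_tibial_insert`): a block with a flat or shallow
  spherical-dish superior surface. The representative footprint is
  43 mm (AP length) × 26.5 mm (ML width). The 43 mm length is the
  published representative-insert value. The width is not published;
  26.5 mm is reconstructed so that the published ML percentages are
  consistent with the published ML millimeters (1.8 mm ≈ 6.8%), and it
  remains configurable. For the same reason, AP coordinates are
  normalized by insert length and ML coordinates by insert width — a
  normalization purely by length cannot reproduce the published ML
  percentages.
* **Cameras** (`dfis_camera_pair`): two point-source/flat-detector
  fluoroscopes with 1000 mm source–detector distance, the object ~700 mm
  from the source, and viewing directions 90° apart — typical C-arm
  geometry in an approximately orthogonal configuration.
* **Trajectories** (`generate_activity_trajectory`): per activity, the
  contact AP/ML path, flexion and tibial internal rotation are keyframed
  and interpolated with a monotone cubic (`splinefun(method =
  "monoH.FC")`), which cannot overshoot between key values — important
  because the keyframes are sparse published way-points. Gait stance is
  keyed on percent of stance (AP: 7.4 → 3.1 → 6.6 → 4.5 mm at
  0/20/80/100%), lunge and sit-to-stand on knee flexion angle
  (sit-to-stand AP: 7.3/0.9/0.7/−0.6 mm at 0/44/76/90°; lunge
  5.8 mm → −0.2 mm by 36° then nearly constant). ML keyframes and the
  stance flexion profile are not published point-by-point; they are
  reconstructions consistent with the published per-activity averages,
  ranges and qualitative descriptions. The femoral pose at each frame is
  constructed exactly (rotation about the torus axis, then internal
  rotation about the vertical through the arc center), so on a flat
  insert the analytic contact point equals the keyframe interpolant —
  this is the pipeline's ground truth. Optional per-parameter Gaussian
  jitter (seeded) emulates tracking noise; all stochastic operations
  take explicit seeds and restore the caller's RNG state.

What the phantom deliberately does **not** emulate: radiographic image
formation (attenuation, scatter, distortion — contours are geometric),
bones and soft tissue, implant-specific asymmetries, and inter-subject
anatomical variability. Tests passing on the phantom therefore validate
the *algorithms* (registration, decomposition, contact search,
statistics), not the clinical measurement chain from real radiographs.

## Silhouette projection and pose estimation

The occluding contour of a watertight mesh is the set of edges whose two
adjacent triangles face oppositely with respect to the ray from the edge
to the X-ray source (perspective-correct, per-edge — not a single view
direction). Contours are sampled proportionally to edge length and
centrally projected onto the detector.

`estimate_pose_dfis` minimizes, over both views, the squared distances
from each measured contour point to the *projected model silhouette
treated as 2D segments*. Using segments rather than sampled model points
removes the sampling-density floor from the cost: for noise-free
contours the cost is exactly zero at the true pose, which is what makes
sub-0.001° recovery possible. The distance is directional (measured
contour → model silhouette) because a measured outline may be partial
while the model silhouette is complete. The optimizer is Nelder–Mead
over the six pose parameters with restarts at the best point (the cost
is non-smooth where the nearest segment switches), a total budget of
2000 evaluations, and convergence declared when the residual RMS falls
below, or stops changing by, 1e-4 mm; non-convergence is flagged, never
silent. A single view is refused outright: out-of-plane depth is
unconstrained. The initialization is assumed within the local basin
(about 5°/10 mm); the benchmarks initialize 2°/2 mm from the truth.

ICP (`icp_align`) is deliberately plain point-to-point: nearest-vertex
correspondences, optional rejection of the worst `trim_fraction`
(partial-overlap robustness, the surrogate for excluding the resected
compartment), and the closed-form SVD update. At the sub-millimeter
registration accuracies relevant here, point-to-plane machinery is not
needed.

## Joint coordinate system

`decompose_6dof` uses a Grood–Suntay-style joint coordinate system:
e1 = femoral ML axis (flexion), e3 = tibial proximal axis
(internal–external rotation), e2 = e3 × e1 floating (adduction). This is
algebraically an intrinsic y–x–z Euler factorization of the relative
rotation, which gives an exact `compose_6dof` inverse (round-trip tested
to 1e-9 on random poses, with global-frame invariance). Translations are
the femoral origin relative to the tibial origin *expressed along the
tibial axes*; the published description does not state the basis, and
the tibial basis is chosen so translations live in the same frame as the
contact coordinates. Configurations with the femoral ML axis within
~2.5° of the tibial long axis raise a gimbal error rather than returning
unstable angles.

Series are resampled for reporting by linear interpolation onto fixed
grids (percent of stance, or flexion angle), without extrapolation.
Non-monotone flexion series (lunge descent/ascent) are split at peak
flexion and the limbs resampled separately and averaged, since reporting
is against flexion angle.

## Contact tracking

The contact point is the insert-superior-surface foot point of the
femoral articular sample point with minimal unsigned distance
(`closest_point_contact`). Taking the point on the *insert* (rather than
the femoral side or the pair midpoint) matches where wear accrues; for
near-contact frames the difference between these choices is below
reporting precision. Reporting the *foot point* keeps the contact
coordinate continuous under insert motion, which is what makes the
sensitivity closed form (below) exact rather than grid-quantized.

When noisy poses push the surfaces into interpenetration, the closest
point is ill-defined; the implementation switches to the point of
maximal penetration depth and reports a negative gap. Distances beyond a
6 mm gap ceiling raise a `no_contact` flag (a distracted joint at that
scale indicates registration failure). Ties within 1e-6 mm resolve to
the lowest-AP point and are flagged.

The search is accelerated by two *exact* bounds — a vertical lower bound
that skips femoral sample points which provably cannot beat the running
best (points below the superior surface, which may penetrate, are never
skipped), and a horizontal lower bound that prunes triangles per sample
point. No approximate spatial index is involved, so the accelerated
result is identical to exhaustive vertex-against-triangle search; the
test suite asserts exact identity over 100 random poses.

Mesh resolution is the accuracy knob: the contact coordinate quantizes
at the support vertex, so its error is bounded by about half the
sagittal chord length (for the default contact mesh, resolution 110,
chord ≈ 0.34 mm). The pipeline therefore uses two meshes built from the
same geometry: a coarse one (resolution 16, ~1000 faces) for silhouette
registration, where the cost minimum does not depend on faceting, and a
fine one for contact. With that split the full noise-free pipeline
(project → register → decompose → contact) reproduces the generator's
ground-truth contact series within 0.2 mm RMS at desk scale.

## Sensitivity analysis

`propagate_pose_noise` perturbs each of the six pose parameters of each
component with independent zero-mean Gaussian draws at the tracking
accuracies (defaults 0.27°/0.10 mm femoral, 0.39°/0.18 mm tibial),
recomputes the contact, and pools the signed AP/ML differences from the
unperturbed contact over frames × replicates into one mean ± SD. Three
documented choices: noise is applied to the Euler parameters (the
tracking errors are quoted per DOF), errors are *signed* (a reported
mean well below the SD implies signed differences, not magnitudes), and
pooling is into a single pair of numbers per direction, matching how
such results are reported. Two analytic anchors are tested: zero noise
gives exactly zero error, and noise on the tibial AP translation alone
co-translates the contact, so the AP error SD equals the injected SD
(verified within 5% at 1000 replicates).

## Statistics

The battery is implemented from first principles and cross-checked
against independent references in the tests, never delegated:

* `ks_normality`: one-sample KS statistic against a normal with
  *sample-estimated* mean and SD; the p-value uses the asymptotic
  Kolmogorov series and is anti-conservative under estimated parameters
  (the classical caveat; the study used the same form).
* `one_way_anova`: F from between/within sums of squares.
* `duncan_posthoc`: ordered means, critical range
  R_p = q(1−α_p, p, df) · √(MS_w/n) with Duncan's protection level
  α_p = 1 − (1−α)^(p−1), outside-in testing with the protection rule
  that no pair inside a non-significant stretch is declared significant,
  harmonic-mean n for mild imbalance (warning beyond 2:1). The
  studentized-range quantile comes from R's `qtukey` (a numerical CDF
  inversion); the stepwise multiple-range procedure is authored here.
  For two groups the decision provably coincides with the pooled t-test
  (q(2, df) = √2·t(df)), which the tests assert case by case; the
  familywise liberality of the procedure is asserted directionally.
* `rank_sum_test`: exact two-sided p by full enumeration of rank
  assignments (midranks for ties) for n ≤ 12 combined, otherwise the
  normal approximation with tie and continuity corrections.

## Problem sizes and reproducibility

The shipped defaults are desk-scale: registration meshes ~1000 faces,
contact meshes ~40k faces, 11-frame stance trajectories, 50-trial
registration benchmarks, and 1000-replicate single-frame sensitivity
runs — sizes chosen so the full pipeline and benchmarks run in minutes
on one core while keeping the quantization error comfortably below the
0.2 mm end-to-end target. Every stochastic stage derives its seed
deterministically from the configured top-level seed, and the run
manifest hashes each stage's result, so identical configurations
reproduce identical outputs bit for bit.

## Known limitations

* The phantom condyle is a torus section and the insert dish is
  spherical; real components are freeform. All accuracy statements about
  the *contact coordinate* transfer only insofar as the real surfaces
  are locally smooth and low-congruence.
* Silhouette registration is local (multi-start within a basin); there
  is no global pose search, and a 180°-symmetric mesh (a symmetric arc
  with no offset) has a mirror-equivalent basin.
* The KS p-value is anti-conservative with estimated parameters, as
  documented; it is used as a screening check.
* Contact area and stress are out of scope — the analysis tracks a
  point, which is exactly what the closest-point definition provides;
  the insert's inferior (backside) surface is not considered.
* The published group-level table is used as the input for the in vivo
  vs in vitro offset arithmetic; patient-level raw data are not
  available, so cohort-level statistics on real data cannot be
  recomputed, only emulated through the phantom.
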