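# ukacontact

Tools for analyzing the in vivo articular contact kinematics of
fixed-bearing medial unicompartmental knee arthroplasty (UKA) from
dual-fluoroscopic imaging, aimed at researchers in musculoskeletal
biomechanics and implant tribology.

Polyethylene (PE) insert wear is a leading failure mode of fixed-bearing
UKA, yet in vitro wear simulators driven by standardized gait loading
reproduce neither the wear regions nor the failure modes seen clinically.
Comparing where the femoral component actually articulates on the insert
in vivo against the wear-region centers measured in vitro requires a
pipeline that can (1) recover six-degree-of-freedom (6-DOF) component
poses from dual ~orthogonal fluoroscopic silhouettes, (2) decompose joint
kinematics, and (3) track the medial articular contact point on the
insert across functional activities. This package implements that
pipeline end to end, together with a synthetic phantom generator so every
stage is testable without patient data.

## What the package computes

* **Phantom generation** — parametric implant surface meshes (a
  toroidal-section femoral condyle, a flat or shallow-dished PE insert on
  the representative 43 x 26.5 mm footprint, a tibial baseplate),
  activity-specific motion trajectories (gait stance, single-leg deep
  lunge, sit-to-stand) whose contact paths follow published key values,
  and a virtual dual-fluoroscope that projects occluding contours onto
  the detectors.
* **Registration** — trimmed point-to-point ICP between meshes
  (`icp_align`, `surface_deviation`), and silhouette-based 6-DOF pose
  estimation: the pose minimizing the sum over both views of squared
  distances from measured contour points to the model's projected
  occluding contour (`estimate_pose_dfis`).
* **Kinematics** — a Grood–Suntay-style joint coordinate system:
  flexion about the femoral medial–lateral axis, internal–external
  rotation about the tibial long axis, adduction about the floating axis;
  translations of the femur along the tibial axes
  (`decompose_6dof`/`compose_6dof`), with left-to-right mirroring and
  phase-grid resampling.
* **Contact** — closest point between the femoral articular surface and
  the insert superior surface (`closest_point_contact`), reported on the
  insert relative to its centroid (anterior+, medial+), normalized by
  insert length (AP) and width (ML), mapped onto the representative
  insert, and summarized per activity as average and range
  (`excursion_summary`), with offsets against in vitro wear-region
  reference centers (`offset_vs_reference`).
* **Sensitivity** — Monte-Carlo propagation of pose-tracking noise
  (0.27°/0.10 mm femoral, 0.39°/0.18 mm tibial, per axis) to
  contact-position error (`propagate_pose_noise`).
* **Statistics** — Kolmogorov–Smirnov normality, one-way ANOVA, Duncan's
  multiple range post hoc test, and the exact/approximate Wilcoxon
  rank-sum test, implemented from first principles (`ks_normality`,
  `one_way_anova`, `duncan_posthoc`, `rank_sum_test`).
* **Orchestration** — `run_pipeline()` executes
  phantom → project → register → decompose → contact → summarize →
  sensitivity → stats from a validated YAML-able configuration and
  returns a hashed, reproducible run manifest.

## Worked example

```r
library(ukacontact)

# implant phantom and the gait-stance trajectory
imp  <- implant_set(femoral_resolution = 80, insert_resolution = 32)
traj <- generate_activity_trajectory("stance", imp, n_frames = 11)

# contact excursion on the insert
ct <- trajectory_contact(traj, imp)
round(ct[c(1, 3, 9, 11), c("phase_key", "ap", "ml", "ap_pct", "gap")], 3)
#>    phase_key    ap    ml ap_pct   gap
#> 1          0 7.290 2.600 16.953 0.000
#> 3         20 3.238 0.895  7.531 0.000
#> 9         80 6.427 2.808 14.946 0.001
#> 11       100 4.513 1.699 10.494 0.000

# per-activity summary and the offset from the in vitro wear center
s <- excursion_summary(list(ct), activity = "stance")
round(s$per_trial[, 1:4], 2)
#>   ap_avg ap_range ml_avg ml_range
#> 1   5.16      4.3   1.85     1.93

off <- offset_vs_reference(invivo_contact_table()$ap_avg_mean,
                           invivo_contact_table()$ml_avg_mean)
round(off$per_subject, 1)
#>   ap_offset ml_offset
#> 1       5.7       1.1
#> 2       1.5       0.2
#> 3       2.6       0.7
```

The contact trace starts 7.4 mm anterior of the insert centroid at heel
strike, glides posteriorly to 3.1 mm at 20% of stance, returns to 6.6 mm
at 80% and ends at 4.5 mm (the generator's keyframes; the small
differences are mesh chord error). The offset report shows the in vivo
contact lying 5.7/1.5/2.6 mm anterior and 1.1/0.2/0.7 mm medial of the
in vitro wear-region center for stance, lunge and sit-to-stand
respectively.

## Vignette

`vignettes/contact-kinematics.Rmd` describes the model and algorithmic
choices: the phantom geometry and its relation to the emulated implant,
the silhouette cost and optimizer, the joint coordinate system and sign
conventions, contact-point definition and penetration handling, the
noise model, and known limitations.
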