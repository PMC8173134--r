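Package: ukacontact
Title: In Vivo Contact Kinematics of Fixed-Bearing Unicompartmental Knee
    Arthroplasty from Dual-Fluoroscopic Silhouettes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to recover six-degree-of-freedom implant poses from
    dual-view fluoroscopic silhouette contours, decompose tibiofemoral
    joint kinematics in a joint coordinate system, and track the medial
    articular contact point on the polyethylene insert of a fixed-bearing
    unicompartmental knee arthroplasty across functional activities
    (gait stance, deep lunge, sit-to-stand). Includes a synthetic phantom
    generator (implant surface meshes, activity motion trajectories,
    perspective silhouette projection), iterative-closest-point mesh
    registration, Monte-Carlo propagation of pose-tracking noise to
    contact-position error, comparison of in vivo contact statistics
    against in vitro wear-region reference centers, and the supporting
    statistical battery (Kolmogorov-Smirnov normality, one-way ANOVA with
    Duncan's multiple range post hoc test, Wilcoxon rank-sum).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
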