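# Six degree-of-freedom joint kinematics in a Grood-Suntay-style joint
# coordinate system: flexion about the femoral medial-lateral axis,
# internal-external rotation about the tibial long axis, adduction about
# the floating axis; translations of the femoral origin expressed along
# the tibial axes.  Component frames: x anterior(+), y medial(+),
# z proximal(+), right-knee convention (left knees are mirrored first).

#' Decompose a femur-tibia pose pair into six degrees of freedom
#'
#' The joint coordinate system takes e1 = femoral ML (y) axis, e3 = tibial
#' proximal (z) axis and the floating e2 = e3 x e1; this is equivalent to
#' an intrinsic y-x-z Euler factorization of the relative rotation.
#' Rotations are reported for the tibia relative to the femur;
#' translations for the femoral origin relative to the tibial origin,
#' expressed along the tibial axes.
#'
#' @param femur_pose,tibia_pose [rigid_pose()] objects giving each
#'   component frame in world coordinates.
#' @param side `"right"` (default) or `"left"`; for left knees the signs
#'   of adduction, internal rotation and ML translation are flipped so
#'   that medial(+) and internal(+) retain their anatomical meaning.
#' @return Named numeric vector: `flexion`, `adduction`,
#'   `internal_rotation` (degrees), `ap`, `pd`, `ml` (mm).
#' @export
decompose_6dof <- function(femur_pose, tibia_pose, side = "right") {
  R <- t(femur_pose$R) %*% tibia_pose$R    # tibia axes in femoral frame
  # gimbal degeneracy: femoral ML axis parallel to tibial long axis
  e1 <- femur_pose$R[, 2]; e3 <- tibia_pose$R[, 3]
  if (abs(sum(e1 * e3)) > 0.999)
    stop("decompose_6dof: gimbal-degenerate configuration (e1 ~ e3)")
  # R = Ry(flex) Rx(add') Rz(int): y-x-z intrinsic
  # row/col expansion gives R[2,3] = -sin(add'), etc.
  b <- asin(max(-1, min(1, -R[2, 3])))
  a <- atan2(R[1, 3], R[3, 3])
  c <- atan2(R[2, 1], R[2, 2])
  ang <- c(a, b, c) * 180 / pi
  d <- femur_pose$t - tibia_pose$t
  tr <- as.numeric(t(tibia_pose$R) %*% d)  # along tibial x (AP), y (ML), z (PD)
  out <- c(flexion = ang[1], adduction = ang[2], internal_rotation = ang[3],
           ap = tr[1], pd = tr[3], ml = tr[2])
  if (identical(side, "left"))
    out[c("adduction", "internal_rotation", "ml")] <-
      -out[c("adduction", "internal_rotation", "ml")]
  out
}

#' Compose a tibial pose from six degrees of freedom
#'
#' Exact inverse of [decompose_6dof()]: given the femoral pose and the six
#' joint values, reconstructs the tibial pose.
#'
#' @param femur_pose femoral [rigid_pose()].
#' @param dof named vector as returned by [decompose_6dof()].
#' @param side `"right"` or `"left"` (see [decompose_6dof()]).
#' @return The tibial [rigid_pose()].
#' @export
compose_6dof <- function(femur_pose, dof, side = "right") {
  dof <- dof[c("flexion", "adduction", "internal_rotation",
               "ap", "pd", "ml")]
  if (identical(side, "left"))
    dof[c("adduction", "internal_rotation", "ml")] <-
      -dof[c("adduction", "internal_rotation", "ml")]
  R_rel <- rot_y(dof[["flexion"]]) %*% rot_x(dof[["adduction"]]) %*%
    rot_z(dof[["internal_rotation"]])
  R_tib <- femur_pose$R %*% R_rel
  d_world <- as.numeric(R_tib %*% c(dof[["ap"]], dof[["ml"]], dof[["pd"]]))
  rigid_pose(R_tib, femur_pose$t - d_world)
}

#' Decompose a whole trajectory into 6-DOF kinematics series
#'
#' @param trajectory a `motion_trajectory`.
#' @param side knee side, `"right"` or `"left"`.
#' @param true_pose use noise-free ground-truth poses?
#' @return Data frame: `phase`, `flexion`, `adduction`,
#'   `internal_rotation` (deg), `ap`, `pd`, `ml` (mm).
#' @export
trajectory_kinematics <- function(trajectory, side = "right",
                                  true_pose = FALSE) {
  n <- length(trajectory$phase)
  out <- t(vapply(seq_len(n), function(i) {
    decompose_6dof(trajectory_pose(trajectory, i, "femur", true_pose),
                   trajectory_pose(trajectory, i, "tibia", true_pose),
                   side = side)
  }, numeric(6)))
  data.frame(phase = trajectory$phase, out)
}

#' Resample a kinematics or contact series onto a reporting phase grid
#'
#' Linear interpolation onto `grid`, with no extrapolation: grid points
#' outside the observed phase range are returned as `NA`.  When the phase
#' axis is knee flexion and the series is non-monotone (lunge descent and
#' ascent), the series is split at peak flexion and the limbs are
#' resampled separately and averaged.
#'
#' @param series data frame whose first column is the phase axis.
#' @param grid numeric vector of output phase values.
#' @param axis `"percent_stance"` or `"flexion_angle"`; flexion allows the
#'   split-at-apex handling.
#' @return Data frame on `grid` with the same value columns.
#' @export
resample_to_phase <- function(series, grid,
                              axis = c("percent_stance", "flexion_angle")) {
  axis <- match.arg(axis)
  if (nrow(series) < 2L) stop("resample_to_phase: need >= 2 samples")
  x <- series[[1]]
  vals <- series[-1]
  interp_block <- function(xs, block) {
    as.data.frame(lapply(block, function(y)
      stats::approx(xs, y, xout = grid, rule = 1)$y))
  }
  if (is.unsorted(x, strictly = TRUE) && is.unsorted(rev(x),
                                                     strictly = TRUE)) {
    if (axis != "flexion_angle")
      stop("resample_to_phase: non-monotone phase on a monotone axis")
    apex <- which.max(x)
    up <- seq_len(apex)
    down <- seq(apex, length(x))
    b1 <- interp_block(x[up], vals[up, , drop = FALSE])
    b2 <- interp_block(rev(x[down]), vals[rev(down), , drop = FALSE])
    out <- as.data.frame(mapply(function(u, v) {
      rowMeans(cbind(u, v), na.rm = TRUE)
    }, b1, b2, SIMPLIFY = FALSE))
    out[is.na(b1) & is.na(b2)] <- NA_real_
  } else {
    if (x[1] > x[length(x)]) {
      x <- rev(x); vals <- vals[rev(seq_len(nrow(vals))), , drop = FALSE]
    }
    out <- interp_block(x, vals)
  }
  cbind(stats::setNames(data.frame(grid), names(series)[1]), out)
}
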