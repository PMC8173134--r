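# Rigid-body poses and the Euler parameterization used for optimization and
# noise injection.  Angles are intrinsic Z-X-Y (rz first, then rx, then ry),
# in degrees; translations in mm.

.deg2rad <- pi / 180
.rad2deg <- 180 / pi

rot_x <- function(deg) {
  a <- deg * .deg2rad
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

rot_y <- function(deg) {
  a <- deg * .deg2rad
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

rot_z <- function(deg) {
  a <- deg * .deg2rad
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Construct a rigid pose
#'
#' A rigid pose maps component-frame coordinates to world coordinates as
#' `x_world = R x_comp + t`.
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 numeric vector (mm).
#' @return An object of class `rigid_pose` with elements `R` and `t`.
#' @export
rigid_pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stop("rigid_pose: non-finite entries")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("rigid_pose: rotation is not a proper orthonormal matrix")
  structure(list(R = rotation, t = translation), class = "rigid_pose")
}

#' @export
print.rigid_pose <- function(x, ...) {
  p <- pose_params(x)
  cat(sprintf(
    "<rigid_pose> angles (Z-X-Y, deg): rx=%.3f ry=%.3f rz=%.3f | t (mm): %.3f %.3f %.3f\n",
    p[1], p[2], p[3], p[4], p[5], p[6]))
  invisible(x)
}

#' Build a rotation matrix from intrinsic Z-X-Y Euler angles (degrees)
#'
#' @param rx,ry,rz angles in degrees; applied intrinsically in the order
#'   Z (rz), then X (rx), then Y (ry): `R = Rz %*% Rx %*% Ry`.
#' @return 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(rx, ry, rz) {
  rot_z(rz) %*% rot_x(rx) %*% rot_y(ry)
}

#' Recover intrinsic Z-X-Y Euler angles (degrees) from a rotation matrix
#'
#' Inverse of [euler_to_matrix()]; well-defined away from gimbal lock
#' (`|rx| < 90` degrees).
#'
#' @param R 3x3 rotation matrix.
#' @return Named numeric vector `c(rx, ry, rz)` in degrees.
#' @export
matrix_to_euler <- function(R) {
  # R = Rz(rz) Rx(rx) Ry(ry); R[3,2] = sin(rx)
  sx <- max(-1, min(1, R[3, 2]))
  rx <- asin(sx)
  if (abs(sx) > 1 - 1e-12) {
    # gimbal: rz and ry degenerate; put all residual rotation in rz
    ry <- 0
    rz <- atan2(R[2, 1], R[1, 1])
  } else {
    rz <- atan2(-R[1, 2], R[2, 2])
    ry <- atan2(-R[3, 1], R[3, 3])
  }
  c(rx = rx, ry = ry, rz = rz) * .rad2deg
}

#' Build a pose from its six optimization parameters
#'
#' @param params numeric vector `c(rx, ry, rz, tx, ty, tz)`; angles in
#'   degrees (intrinsic Z-X-Y), translations in mm.
#' @return A [rigid_pose()].
#' @export
pose_from_params <- function(params) {
  stopifnot(length(params) == 6L)
  rigid_pose(euler_to_matrix(params[1], params[2], params[3]), params[4:6])
}

#' Extract the six pose parameters
#'
#' @param pose a [rigid_pose()].
#' @return Named numeric vector `c(rx, ry, rz, tx, ty, tz)`.
#' @export
pose_params <- function(pose) {
  ang <- matrix_to_euler(pose$R)
  c(ang, tx = pose$t[1], ty = pose$t[2], tz = pose$t[3])
}

#' Compose two poses
#'
#' `pose_compose(a, b)` returns the pose applying `b` first, then `a`.
#'
#' @param a,b [rigid_pose()] objects.
#' @return A [rigid_pose()].
#' @export
pose_compose <- function(a, b) {
  rigid_pose(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a pose
#' @param pose a [rigid_pose()].
#' @return The inverse [rigid_pose()].
#' @export
pose_invert <- function(pose) {
  rigid_pose(t(pose$R), as.numeric(-t(pose$R) %*% pose$t))
}

#' Apply a pose to points
#'
#' @param pose a [rigid_pose()].
#' @param points n x 3 matrix of points (rows), or a length-3 vector.
#' @return Transformed points, same shape as input.
#' @export
pose_apply <- function(pose, points) {
  if (is.null(dim(points))) {
    as.numeric(pose$R %*% points) + pose$t
  } else {
    sweep(points %*% t(pose$R), 2, pose$t, "+")
  }
}

#' Relative pose of b with respect to a
#'
#' Returns the pose `p` such that `a * p = b`, i.e. the transform from
#' frame b coordinates into frame a coordinates.
#'
#' @param a,b [rigid_pose()] objects.
#' @return A [rigid_pose()].
#' @export
pose_relative <- function(a, b) {
  pose_compose(pose_invert(a), b)
}
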