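# Activity motion trajectories.  The generator drives the femoral component
# over the insert so that the condyle's lowest articular point follows
# keyframed contact coordinates while flexion and tibial internal rotation
# follow keyframed profiles; the tibial component is the world frame.
# Keyframe interpolation is monotone cubic (no overshoot between key
# values), via stats::splinefun(method = "monoH.FC").

#' Default activity keyframes
#'
#' Contact AP keyframes encode the reported contact trajectories: during
#' gait stance the AP contact moves 7.4 mm -> 3.1 mm (0-20%), back to
#' 6.6 mm at 80% and 4.5 mm at 100%; during sit-to-stand 7.3 mm at 0
#' degrees flexion to 0.9 at 44, 0.7 at 76 and -0.6 at 90; during lunge
#' 5.8 mm at 0 degrees to -0.2 at 36, then nearly constant.  ML keyframes
#' and the flexion/rotation profiles are reconstructions consistent with
#' the reported per-activity averages and ranges.
#'
#' @param activity one of `"stance"`, `"lunge"`, `"sit_to_stand"`.
#' @return Data frame with columns `phase`, `ap`, `ml`, `flexion`,
#'   `internal_rotation`.  `phase` is percent of stance for gait and knee
#'   flexion (degrees) otherwise.
#' @export
default_keyframes <- function(activity = c("stance", "lunge",
                                           "sit_to_stand")) {
  activity <- match.arg(activity)
  switch(activity,
    stance = data.frame(
      phase = c(0, 20, 50, 80, 100),
      ap = c(7.4, 3.1, 5.0, 6.6, 4.5),
      ml = c(2.6, 0.9, 1.6, 2.8, 1.7),
      flexion = c(5, 18, 8, 15, 38),
      internal_rotation = c(0, 2, 1, 2.5, 4)),
    lunge = data.frame(
      phase = c(0, 36, 70, 100),
      ap = c(5.8, -0.2, -0.2, -0.3),
      ml = c(2.2, 0.6, 0.4, -0.2),
      flexion = c(0, 36, 70, 100),
      internal_rotation = c(0, 3, 5, 6)),
    sit_to_stand = data.frame(
      phase = c(0, 44, 76, 90),
      ap = c(7.3, 0.9, 0.7, -0.6),
      ml = c(2.6, 1.1, 0.9, 0.4),
      flexion = c(0, 44, 76, 90),
      internal_rotation = c(0, 3, 4.5, 5)))
}

#' Generate a synthetic activity motion trajectory
#'
#' Builds a smooth pose sequence in which the femoral component's lowest
#' articular point tracks the keyframed contact AP/ML coordinates over the
#' insert superior surface, while flexion and tibial internal rotation
#' follow their keyframed profiles.  Optional zero-mean Gaussian jitter
#' (per pose parameter, seeded) emulates tracking noise; the noise-free
#' poses are kept alongside as ground truth.
#'
#' @param activity `"stance"`, `"lunge"` or `"sit_to_stand"`.
#' @param implants an [implant_set()].
#' @param keyframes data frame as returned by [default_keyframes()]; must
#'   be sorted by `phase` with at least 2 rows.
#' @param n_frames number of frames (>= number of keyframes).
#' @param noise_sd per-DOF jitter SD: scalar or length-12 vector ordered
#'   (femur rx, ry, rz, tx, ty, tz, tibia rx, ..., tz); degrees and mm.
#' @param seed RNG seed for the jitter.
#' @return Object of class `motion_trajectory`: `activity`, `phase`,
#'   `poses` (data frame of 12 pose parameters per frame), `poses_true`
#'   (noise-free), `truth` (keyframe-interpolated contact and angles).
#' @export
generate_activity_trajectory <- function(activity, implants,
                                         keyframes = NULL, n_frames = 21,
                                         noise_sd = 0, seed = 1) {
  if (is.null(keyframes)) keyframes <- default_keyframes(activity)
  if (nrow(keyframes) < 2L || is.unsorted(keyframes$phase, strictly = TRUE))
    stop("generate_activity_trajectory: keyframes must be >= 2, sorted")
  if (n_frames < nrow(keyframes))
    stop("generate_activity_trajectory: n_frames < number of keyframes")
  ins <- implants$insert
  if (any(abs(keyframes$ap) > ins$length / 2) ||
      any(abs(keyframes$ml) > ins$width / 2))
    stop("generate_activity_trajectory: keyframe contact outside insert footprint")
  phase <- seq(min(keyframes$phase), max(keyframes$phase),
               length.out = n_frames)
  mono <- function(y) stats::splinefun(keyframes$phase, y,
                                       method = "monoH.FC")(phase)
  ap <- mono(keyframes$ap)
  ml <- mono(keyframes$ml)
  flex <- mono(keyframes$flexion)
  irot <- mono(keyframes$internal_rotation)
  rs <- implants$femoral_condyle$sagittal_radius
  top_z <- function(x, y) {
    if (is.infinite(ins$dish_radius)) rep(ins$thickness, length(x)) else
      ins$thickness + (ins$dish_radius -
                         sqrt(ins$dish_radius^2 - x^2 - y^2))
  }
  # Femoral rotation Rz(-irot) Ry(-flex) keeps the condyle's lowest point
  # directly below the torus center (the torus axis stays horizontal), so
  # placing the center at height rs above the surface point realises the
  # keyframed contact exactly on a flat insert.
  n <- length(phase)
  poses <- matrix(0, n, 12)
  colnames(poses) <- c("fem_rx", "fem_ry", "fem_rz", "fem_tx", "fem_ty",
                       "fem_tz", "tib_rx", "tib_ry", "tib_rz", "tib_tx",
                       "tib_ty", "tib_tz")
  for (i in seq_len(n)) {
    R <- rot_z(-irot[i]) %*% rot_y(-flex[i])
    ang <- matrix_to_euler(R)
    poses[i, 1:3] <- ang
    poses[i, 4:6] <- c(ap[i] + ins$centroid[1], ml[i] + ins$centroid[2],
                       top_z(ap[i], ml[i]) + rs)
  }
  poses_true <- poses
  if (any(noise_sd > 0)) {
    sd12 <- if (length(noise_sd) == 1L) rep(noise_sd, 12) else noise_sd
    if (length(sd12) != 12L)
      stop("generate_activity_trajectory: noise_sd must be length 1 or 12")
    poses <- poses + with_seed(seed, matrix(stats::rnorm(n * 12, 0,
                                                         rep(sd12, each = n)),
                                            n, 12))
  }
  structure(list(activity = activity, phase = phase,
                 poses = as.data.frame(poses),
                 poses_true = as.data.frame(poses_true),
                 truth = data.frame(phase = phase, ap = ap, ml = ml,
                                    flexion = flex,
                                    internal_rotation = irot),
                 keyframes = keyframes),
            class = "motion_trajectory")
}

#' @export
print.motion_trajectory <- function(x, ...) {
  cat(sprintf("<motion_trajectory> %s, %d frames, phase %.1f-%.1f\n",
              x$activity, length(x$phase), min(x$phase), max(x$phase)))
  invisible(x)
}

#' Extract the rigid pose of one component at one frame
#'
#' @param trajectory a `motion_trajectory`.
#' @param frame frame index.
#' @param component `"femur"` or `"tibia"`.
#' @param true_pose use the noise-free ground-truth pose?
#' @return A [rigid_pose()].
#' @export
trajectory_pose <- function(trajectory, frame,
                            component = c("femur", "tibia"),
                            true_pose = FALSE) {
  component <- match.arg(component)
  src <- if (true_pose) trajectory$poses_true else trajectory$poses
  cols <- if (component == "femur") 1:6 else 7:12
  pose_from_params(as.numeric(src[frame, cols]))
}
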