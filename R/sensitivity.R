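# Monte-Carlo propagation of pose-tracking noise to contact-position error:
# each of the six pose parameters of each component is perturbed by
# independent zero-mean Gaussian draws at the tracking-accuracy SDs, the
# contact point is recomputed, and the signed AP/ML differences from the
# unperturbed contact are pooled over frames and replicates.

#' Pose-noise specification
#'
#' Per-axis, independent zero-mean Gaussian noise applied to the Euler
#' angles (degrees) and translations (mm) of each component.  Defaults are
#' the dual-fluoroscopy tracking accuracies: 0.27 degrees / 0.10 mm for
#' the femoral condyle and 0.39 degrees / 0.18 mm for the tibial
#' baseplate.
#'
#' @param femur_rot_sd,femur_trans_sd,tibia_rot_sd,tibia_trans_sd SDs
#'   (degrees, mm); all >= 0.  Scalars apply to all three axes; a length-3
#'   vector gives per-axis SDs (order: the three Euler angles rx, ry, rz,
#'   or translations tx = AP, ty = ML, tz = PD).
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(femur_rot_sd = 0.27, femur_trans_sd = 0.10,
                       tibia_rot_sd = 0.39, tibia_trans_sd = 0.18) {
  vals <- list(femur_rot_sd, femur_trans_sd, tibia_rot_sd, tibia_trans_sd)
  if (any(unlist(vals) < 0)) stop("noise_spec: SDs must be >= 0")
  if (!all(lengths(vals) %in% c(1L, 3L)))
    stop("noise_spec: SDs must be scalars or length-3 vectors")
  structure(list(femur_rot_sd = femur_rot_sd,
                 femur_trans_sd = femur_trans_sd,
                 tibia_rot_sd = tibia_rot_sd,
                 tibia_trans_sd = tibia_trans_sd), class = "noise_spec")
}

# 12-vector of per-parameter SDs in pose-parameter order
.noise_sd12 <- function(noise) {
  c(rep(noise$femur_rot_sd, length.out = 3),
    rep(noise$femur_trans_sd, length.out = 3),
    rep(noise$tibia_rot_sd, length.out = 3),
    rep(noise$tibia_trans_sd, length.out = 3))
}

#' Propagate pose noise to contact-position error
#'
#' For each frame x replicate, perturbs the six pose parameters of both
#' components with independent Gaussian draws (seeded), recomputes the
#' closest-point contact, and accumulates the signed AP and ML differences
#' from the unperturbed contact.  Reported as mean and SD pooled over all
#' frames and replicates.
#'
#' @param trajectory a `motion_trajectory` whose frames are in contact.
#' @param implants an [implant_set()].
#' @param noise a [noise_spec()].
#' @param n_replicates replicates per frame (>= 1).
#' @param seed RNG seed; the report is deterministic given the seed.
#' @param gap_ceiling mm, see [closest_point_contact()].
#' @param frames optional frame subset (indices); default all frames.
#' @return Object of class `sensitivity_report`: `ap_error_mean`,
#'   `ap_error_sd`, `ml_error_mean`, `ml_error_sd` (mm), `n_frames`,
#'   `n_replicates`, `seed`, `n_no_contact`.
#' @export
propagate_pose_noise <- function(trajectory, implants, noise = noise_spec(),
                                 n_replicates = 100, seed = 1,
                                 gap_ceiling = 6, frames = NULL) {
  if (n_replicates < 1) stop("propagate_pose_noise: n_replicates >= 1")
  if (is.null(frames)) frames <- seq_along(trajectory$phase)
  ins <- implants$insert
  sd12 <- .noise_sd12(noise)
  base <- lapply(frames, function(i) {
    fp <- trajectory_pose(trajectory, i, "femur", true_pose = TRUE)
    tp <- trajectory_pose(trajectory, i, "tibia", true_pose = TRUE)
    fem <- transform_mesh(implants$femoral_condyle,
                          pose_compose(pose_invert(tp), fp),
                          "tibial_component")
    rec <- closest_point_contact(fem, ins, gap_ceiling)
    if (rec$no_contact)
      stop("propagate_pose_noise: reference frame not in contact")
    list(fp = pose_params(fp), tp = pose_params(tp),
         ap = rec$ap, ml = rec$ml)
  })
  draws <- with_seed(seed, matrix(stats::rnorm(
    length(frames) * n_replicates * 12, 0, rep(sd12, each = 1)),
    ncol = 12, byrow = TRUE))
  ap_err <- numeric(0); ml_err <- numeric(0)
  n_no_contact <- 0L
  row <- 0L
  for (bi in seq_along(base)) {
    b <- base[[bi]]
    for (r in seq_len(n_replicates)) {
      row <- row + 1L
      fp <- pose_from_params(b$fp + draws[row, 1:6])
      tp <- pose_from_params(b$tp + draws[row, 7:12])
      fem <- transform_mesh(implants$femoral_condyle,
                            pose_compose(pose_invert(tp), fp),
                            "tibial_component")
      rec <- closest_point_contact(fem, ins, gap_ceiling)
      if (rec$no_contact) {
        n_no_contact <- n_no_contact + 1L
        next
      }
      ap_err <- c(ap_err, rec$ap - b$ap)
      ml_err <- c(ml_err, rec$ml - b$ml)
    }
  }
  if (!length(ap_err))
    stop("propagate_pose_noise: all perturbed frames lost contact")
  structure(list(ap_error_mean = mean(ap_err),
                 ap_error_sd = if (length(ap_err) > 1)
                   stats::sd(ap_err) else 0,
                 ml_error_mean = mean(ml_err),
                 ml_error_sd = if (length(ml_err) > 1)
                   stats::sd(ml_err) else 0,
                 n_frames = length(frames), n_replicates = n_replicates,
                 seed = seed, n_no_contact = n_no_contact),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf(
    "<sensitivity_report> AP %.3f +/- %.3f mm, ML %.3f +/- %.3f mm (%d frames x %d reps)\n",
    x$ap_error_mean, x$ap_error_sd, x$ml_error_mean, x$ml_error_sd,
    x$n_frames, x$n_replicates))
  invisible(x)
}
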