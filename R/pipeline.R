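# End-to-end orchestration: phantom -> silhouette projection -> pose
# registration -> 6-DOF decomposition -> contact tracking -> excursion
# summary and wear-reference offsets -> pose-noise sensitivity -> group
# statistics.  Every stage writes CSV/JSON artifacts and is logged in a
# run manifest whose hashes make determinism checkable.

hash_object <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the full contact-kinematics pipeline
#'
#' Executes, per configured activity: trajectory generation, dual-view
#' silhouette projection, silhouette-based pose recovery (optional),
#' 6-DOF decomposition, contact tracking and excursion summaries; then
#' the in vivo vs in vitro offset report, the Monte-Carlo pose-noise
#' sensitivity analysis, and (optionally) multi-subject group statistics.
#' Any stage error halts the run with the stage name.
#'
#' @param config configuration list (see [default_config()]); validated
#'   with [validate_config()].
#' @return A run manifest (class `run_manifest`): configuration hash,
#'   package version, per-stage timings, warnings, artifact file list and
#'   result hashes; the stage results themselves are attached as
#'   `results`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  out_dir <- cfg$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  manifest <- list(config_hash = hash_object(cfg),
                   package_version =
                     as.character(utils::packageVersion("ukacontact")),
                   stages = list(), files = character(0))
  results <- list()
  warn_count <- 0L
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e)
        stop(sprintf("pipeline stage '%s' failed: %s", name,
                     conditionMessage(e)), call. = FALSE)),
      warning = function(w) {
        warn_count <<- warn_count + 1L
        invokeRestart("muffleWarning")
      })
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      hash = hash_object(res))
    results[[name]] <<- res
    res
  }
  emit <- function(obj, file, writer) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, file)
    writer(obj, path)
    manifest$files <<- c(manifest$files, path)
  }

  ph <- cfg$phantom
  implants_reg <- run_stage("phantom", function() {
    implant_set(insert_length = ph$insert_length,
                insert_width = ph$insert_width,
                dish_radius = ph$dish_radius,
                sagittal_radius = ph$sagittal_radius,
                coronal_radius = ph$coronal_radius,
                arc_span = ph$arc_span, arc_offset = ph$arc_offset,
                femoral_resolution = ph$registration_resolution,
                insert_resolution = 16)
  })
  # fine meshes for the contact stage
  implants_fine <- implant_set(
    insert_length = ph$insert_length, insert_width = ph$insert_width,
    dish_radius = ph$dish_radius, sagittal_radius = ph$sagittal_radius,
    coronal_radius = ph$coronal_radius, arc_span = ph$arc_span,
    arc_offset = ph$arc_offset,
    femoral_resolution = ph$contact_resolution,
    insert_resolution = ph$insert_resolution)
  cams <- dfis_camera_pair(cfg$cameras$source_detector_distance,
                           cfg$cameras$object_distance, cfg$cameras$angle)
  baseplate_reg <- implants_reg$baseplate

  trajectories <- run_stage("trajectories", function() {
    out <- lapply(cfg$activities$names, function(act)
      generate_activity_trajectory(
        act, implants_fine, n_frames = cfg$activities$n_frames,
        noise_sd = cfg$activities$noise_sd,
        seed = derive_seed(cfg$seed, paste0("traj_", act))))
    names(out) <- cfg$activities$names
    out
  })
  for (act in names(trajectories))
    emit(trajectories[[act]], sprintf("trajectory_%s.csv", act),
         write_poses)

  contours <- run_stage("project", function() {
    lapply(trajectories, function(traj) {
      lapply(seq_along(traj$phase), function(i) {
        lapply(seq_along(cams), function(k) {
          fem <- trajectory_pose(traj, i, "femur")
          tib <- trajectory_pose(traj, i, "tibia")
          list(femur = project_silhouette(implants_reg$femoral_condyle,
                                          fem, cams[[k]],
                                          cfg$cameras$n_contour_points),
               tibia = project_silhouette(baseplate_reg, tib, cams[[k]],
                                          cfg$cameras$n_contour_points))
        })
      })
    })
  })

  poses_out <- run_stage("register", function() {
    if (!cfg$registration$enabled) {
      lapply(trajectories, function(traj) traj$poses)
    } else {
      rg <- cfg$registration
      ocfg <- list(max_eval = rg$max_eval, restarts = rg$restarts,
                   tol = rg$tol)
      lapply(names(trajectories), function(act) {
        traj <- trajectories[[act]]
        cts <- contours[[act]]
        n <- length(traj$phase)
        est <- traj$poses
        prev_f <- prev_t <- NULL
        perturb <- with_seed(derive_seed(cfg$seed, paste0("reg_", act)), {
          matrix(stats::rnorm(12, 0,
                              rep(c(rg$init_rot_perturb,
                                    rg$init_trans_perturb), each = 3) / 2),
                 1)
        })
        for (i in seq_len(n)) {
          init_f <- if (is.null(prev_f))
            pose_from_params(as.numeric(traj$poses[i, 1:6]) +
                               as.numeric(perturb)[1:6]) else prev_f
          init_t <- if (is.null(prev_t))
            pose_from_params(as.numeric(traj$poses[i, 7:12]) +
                               as.numeric(perturb)[7:12]) else prev_t
          rf <- estimate_pose_dfis(
            implants_reg$femoral_condyle,
            lapply(cts[[i]], `[[`, "femur"), cams, init_f, ocfg)
          rt <- estimate_pose_dfis(
            baseplate_reg, lapply(cts[[i]], `[[`, "tibia"), cams,
            init_t, ocfg)
          est[i, 1:6] <- pose_params(rf$pose)
          est[i, 7:12] <- pose_params(rt$pose)
          prev_f <- rf$pose; prev_t <- rt$pose
        }
        est
      }) -> out
      names(out) <- names(trajectories)
      out
    }
  })

  registered <- lapply(names(trajectories), function(act) {
    traj <- trajectories[[act]]
    traj$poses <- poses_out[[act]]
    traj
  })
  names(registered) <- names(trajectories)

  kin <- run_stage("kinematics", function() {
    lapply(registered, trajectory_kinematics)
  })
  for (act in names(kin))
    emit(kin[[act]], sprintf("kinematics_%s.csv", act), function(obj, p)
      write_table(obj, p, units = "flexion/adduction/internal_rotation deg; ap/pd/ml mm"))

  contact <- run_stage("contact", function() {
    lapply(registered, function(traj)
      trajectory_contact(traj, implants_fine))
  })
  for (act in names(contact))
    emit(contact[[act]], sprintf("contact_%s.csv", act), function(obj, p)
      write_table(obj, p, units = "ap/ml mm from insert centroid; pct of insert length/width"))

  summaries <- run_stage("summarize", function() {
    per_act <- lapply(names(contact), function(act)
      excursion_summary(list(contact[[act]]), activity = act,
                        insert_length = implants_fine$insert_length,
                        insert_width = implants_fine$insert_width))
    names(per_act) <- names(contact)
    # Table-1-shaped block: activities x {average, range} x {AP, ML}
    tab <- do.call(rbind, lapply(per_act, function(s) {
      pt <- s$per_trial
      data.frame(activity = s$activity,
                 ap_avg = mean(pt$ap_avg), ap_avg_pct = mean(pt$ap_avg_pct),
                 ap_range = mean(pt$ap_range),
                 ap_range_pct = mean(pt$ap_range_pct),
                 ml_avg = mean(pt$ml_avg), ml_avg_pct = mean(pt$ml_avg_pct),
                 ml_range = mean(pt$ml_range),
                 ml_range_pct = mean(pt$ml_range_pct))
    }))
    ref <- wear_reference_center()
    offs <- offset_vs_reference(tab$ap_avg, tab$ml_avg, ref)
    list(per_activity = per_act, table = tab,
         offsets = cbind(activity = tab$activity, offs$per_subject))
  })
  emit(summaries$table, "contact_summary.csv", function(obj, p)
    write_table(obj, p, units = "per-activity contact excursion summary"))
  emit(summaries$offsets, "contact_offsets.csv", function(obj, p)
    write_table(obj, p, units = "offset = in vivo minus in vitro reference (mm)"))

  if (cfg$sensitivity$enabled) {
    sens <- run_stage("sensitivity", function() {
      ns <- cfg$sensitivity$noise
      propagate_pose_noise(
        trajectories[[1]], implants_fine,
        noise_spec(ns$femur_rot_sd, ns$femur_trans_sd, ns$tibia_rot_sd,
                   ns$tibia_trans_sd),
        n_replicates = cfg$sensitivity$n_replicates,
        seed = derive_seed(cfg$seed, "sensitivity"))
    })
    emit(unclass(sens), "sensitivity.json", function(obj, p)
      jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA))
  }

  if (cfg$stats$enabled) {
    stats_res <- run_stage("stats", function() {
      # published-table offset report (the packaged reference values)
      pub <- published_contact_offsets()
      out <- list(published_offsets = pub)
      if (cfg$stats$n_subjects >= 2) {
        # emulate a cohort: subject-level shifts of the contact keyframes
        tabref <- invivo_contact_table()
        subj <- with_seed(derive_seed(cfg$seed, "stats"), {
          lapply(seq_len(cfg$stats$n_subjects), function(s) {
            vapply(seq_len(3), function(ai)
              stats::rnorm(1, tabref$ap_avg_mean[ai], tabref$ap_avg_sd[ai]),
              0)
          })
        })
        per_act <- lapply(1:3, function(ai)
          vapply(subj, `[[`, 0, ai))
        names(per_act) <- tabref$activity
        fit <- one_way_anova(per_act)
        out$anova <- fit
        out$duncan <- duncan_posthoc(per_act, alpha = cfg$stats$alpha)
        ref <- wear_reference_center()
        out$rank_sum <- rank_sum_test(per_act$stance,
                                      rep(ref$ap_mm, length(per_act$stance)))
        out$ks <- lapply(per_act, ks_normality)
      }
      out
    })
    emit(stats_res$published_offsets, "published_offsets.csv",
         function(obj, p)
           write_table(obj, p, units = "published in vivo minus in vitro offsets (mm)"))
  }

  manifest$warnings <- warn_count
  manifest$results <- results
  structure(manifest, class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> config %s, %d stage(s), %d warning(s)\n",
              substr(x$config_hash, 1, 8), length(x$stages), x$warnings))
  for (nm in names(x$stages))
    cat(sprintf("  %-12s %7.2fs  %s\n", nm, x$stages[[nm]]$seconds,
                substr(x$stages[[nm]]$hash, 1, 8)))
  invisible(x)
}
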