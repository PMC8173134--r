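# Pipeline configuration: a nested list, schema-validated against the
# defaults (unknown keys rejected), read/written as YAML.  Every
# stochastic stage derives its seed deterministically from the top-level
# seed.

#' Default pipeline configuration
#'
#' @return Nested list with blocks `phantom`, `cameras`, `activities`,
#'   `registration`, `sensitivity`, `stats`, plus `seed` and
#'   `output_dir`.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = NULL,
    phantom = list(
      insert_length = 43, insert_width = 26.5, dish_radius = Inf,
      insert_thickness = 8, sagittal_radius = 24, coronal_radius = 11,
      arc_span = 150, arc_offset = -25,
      registration_resolution = 16, contact_resolution = 110,
      insert_resolution = 40),
    cameras = list(source_detector_distance = 1000, object_distance = 700,
                   angle = 90, n_contour_points = 120),
    activities = list(names = c("stance", "lunge", "sit_to_stand"),
                      n_frames = 11, noise_sd = 0),
    registration = list(enabled = TRUE, max_eval = 2000, restarts = 4,
                        tol = 1e-4, init_rot_perturb = 2,
                        init_trans_perturb = 2),
    sensitivity = list(enabled = TRUE, n_replicates = 50,
                       noise = list(femur_rot_sd = 0.27,
                                    femur_trans_sd = 0.10,
                                    tibia_rot_sd = 0.39,
                                    tibia_trans_sd = 0.18)),
    stats = list(enabled = TRUE, alpha = 0.05, n_subjects = 0))
}

check_unknown_keys <- function(cfg, ref, path = "") {
  if (!is.list(cfg)) return(invisible(NULL))
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra))
    stop("config: unknown key(s): ",
         paste0(path, extra, collapse = ", "))
  for (k in intersect(names(cfg), names(ref)))
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])))
      check_unknown_keys(cfg[[k]], ref[[k]], paste0(path, k, "."))
  invisible(NULL)
}

#' Validate and complete a pipeline configuration
#'
#' Unknown keys are rejected; missing keys are filled from
#' [default_config()].
#'
#' @param config partial configuration list.
#' @return Completed configuration list.
#' @export
validate_config <- function(config = list()) {
  ref <- default_config()
  check_unknown_keys(config, ref)
  cfg <- utils::modifyList(ref, config)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    stop("config: seed must be a single number")
  bad <- setdiff(cfg$activities$names, c("stance", "lunge", "sit_to_stand"))
  if (length(bad)) stop("config: unknown activity ", paste(bad, collapse = ", "))
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config configuration list (write).
#' @return Validated configuration list (read); `path` invisibly (write).
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
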