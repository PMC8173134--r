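test_that("zero noise gives exactly zero contact error", {
  imp <- small_implants(femoral_resolution = 40, insert_resolution = 24)
  traj <- generate_activity_trajectory("stance", imp, n_frames = 5)
  rep <- propagate_pose_noise(traj, imp, noise_spec(0, 0, 0, 0),
                              n_replicates = 3, seed = 5)
  expect_identical(c(rep$ap_error_mean, rep$ap_error_sd,
                     rep$ml_error_mean, rep$ml_error_sd), rep(0, 4))
})

test_that("pure tibial AP translation noise shifts the contact rigidly (closed form)", {
  imp <- small_implants(femoral_resolution = 60, insert_resolution = 24)
  traj <- generate_activity_trajectory("stance", imp, n_frames = 5)
  rep <- propagate_pose_noise(traj, imp,
                              noise_spec(0, 0, 0, c(0.18, 0, 0)),
                              n_replicates = 150, seed = 9, frames = 2)
  # contact co-translates: AP error is minus the draw, exactly
  expect_lt(abs(rep$ap_error_mean), 0.05)
  expect_lt(abs(rep$ap_error_sd - 0.18), 0.02)
  expect_lt(max(abs(c(rep$ml_error_mean, rep$ml_error_sd))), 1e-12)
})

test_that("the sensitivity report is deterministic given the seed", {
  imp <- small_implants(femoral_resolution = 40, insert_resolution = 20)
  traj <- generate_activity_trajectory("stance", imp, n_frames = 5)
  r1 <- propagate_pose_noise(traj, imp, noise_spec(), n_replicates = 10,
                             seed = 33)
  r2 <- propagate_pose_noise(traj, imp, noise_spec(), n_replicates = 10,
                             seed = 33)
  expect_identical(r1, r2)
  r3 <- propagate_pose_noise(traj, imp, noise_spec(), n_replicates = 10,
                             seed = 34)
  expect_false(identical(r1$ap_error_sd, r3$ap_error_sd))
})

test_that("contact error shrinks with the noise scale, approximately linearly", {
  imp <- small_implants(femoral_resolution = 60, insert_resolution = 24)
  traj <- generate_activity_trajectory("stance", imp, n_frames = 5)
  sds <- vapply(c(1, 0.5, 0.25), function(s) {
    r <- propagate_pose_noise(
      traj, imp, noise_spec(0.27 * s, 0.10 * s, 0.39 * s, 0.18 * s),
      n_replicates = 120, seed = 13, frames = 2)
    sqrt(r$ap_error_sd^2 + r$ml_error_sd^2)
  }, 0)
  expect_true(all(diff(sds) < 0))
  # low-curvature geometry: halving the SDs roughly halves the error SD
  expect_equal(sds[2] / sds[1], 0.5, tolerance = 0.2)
  expect_equal(sds[3] / sds[2], 0.5, tolerance = 0.2)
})

test_that("invalid sensitivity inputs are rejected", {
  expect_error(noise_spec(-1, 0, 0, 0), ">= 0")
  expect_error(noise_spec(c(1, 1), 0, 0, 0), "length-3")
  imp <- small_implants(femoral_resolution = 40, insert_resolution = 20)
  traj <- generate_activity_trajectory("stance", imp, n_frames = 5)
  expect_error(propagate_pose_noise(traj, imp, noise_spec(),
                                    n_replicates = 0), "n_replicates")
})
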