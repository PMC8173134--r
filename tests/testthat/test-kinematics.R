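test_that("6-DOF decomposition handles the canonical trivial cases", {
  id <- rigid_pose()
  expect_equal(unname(decompose_6dof(id, id)), rep(0, 6), tolerance = 1e-12)
  # tibia rotated 30 degrees about the femoral ML axis
  dof <- decompose_6dof(id, pose_from_params(c(0, 30, 0, 0, 0, 0)))
  expect_equal(dof[["flexion"]], 30, tolerance = 1e-9)
  expect_lt(max(abs(dof[c("adduction", "internal_rotation", "ap", "pd",
                          "ml")])), 1e-9)
  # femur translated +5 mm along the tibial anterior axis
  dof <- decompose_6dof(rigid_pose(translation = c(5, 0, 0)), id)
  expect_equal(dof[["ap"]], 5, tolerance = 1e-12)
  expect_lt(max(abs(dof[c("flexion", "adduction", "internal_rotation",
                          "pd", "ml")])), 1e-12)
})

test_that("decompose-compose round-trips on random poses", {
  set.seed(31)
  for (i in 1:200) {
    fp <- pose_from_params(c(runif(3, -60, 60), runif(3, -30, 30)))
    tp <- pose_from_params(c(runif(3, -60, 60), runif(3, -30, 30)))
    dof <- tryCatch(decompose_6dof(fp, tp), error = function(e) NULL)
    if (is.null(dof)) next   # gimbal-degenerate draw
    tp2 <- compose_6dof(fp, dof)
    expect_lt(max(abs(tp2$R - tp$R)), 1e-9)
    expect_lt(max(abs(tp2$t - tp$t)), 1e-9)
  }
})

test_that("all six DOF are invariant to a global rigid transform of both components", {
  set.seed(32)
  for (i in 1:25) {
    fp <- pose_from_params(c(runif(3, -40, 40), runif(3, -30, 30)))
    tp <- pose_from_params(c(runif(3, -40, 40), runif(3, -30, 30)))
    G <- pose_from_params(c(runif(3, -90, 90), runif(3, -100, 100)))
    d0 <- tryCatch(decompose_6dof(fp, tp), error = function(e) NULL)
    if (is.null(d0)) next
    d1 <- decompose_6dof(pose_compose(G, fp), pose_compose(G, tp))
    expect_equal(unname(d1), unname(d0), tolerance = 1e-9)
  }
})

test_that("gimbal-degenerate configurations raise an error", {
  # femoral ML axis aligned with tibial long axis: rotate femur 90 deg
  fp <- pose_from_params(c(90, 0, 0, 0, 0, 0))
  expect_error(decompose_6dof(fp, rigid_pose()), "gimbal")
})

test_that("resampling is exact for constants and linear ramps", {
  s <- data.frame(phase = c(0, 100), v = c(3, 3))
  out <- resample_to_phase(s, grid = c(0, 25, 50, 100))
  expect_equal(out$v, rep(3, 4))
  s <- data.frame(phase = c(0, 100), v = c(0, 10))
  out <- resample_to_phase(s, grid = c(0, 50, 100))
  expect_equal(out$v, c(0, 5, 10))
  # no extrapolation: clipped-out points are NA
  out <- resample_to_phase(s, grid = c(-10, 50, 120))
  expect_true(is.na(out$v[1]) && is.na(out$v[3]))
  expect_error(resample_to_phase(s[1, , drop = FALSE], grid = 0), ">= 2")
})

test_that("linear resampling error of a sinusoid respects the interpolation bound", {
  x <- seq(0, 10, by = 0.5)
  s <- data.frame(phase = x, v = sin(x))
  fine <- resample_to_phase(s, grid = seq(0, 10, by = 0.25))
  back <- resample_to_phase(data.frame(phase = fine$phase, v = fine$v),
                            grid = x)
  h <- 0.5
  expect_lt(max(abs(back$v - sin(x))), h^2 * 1 / 8 + 1e-12)
})

test_that("non-monotone flexion series are split at the apex and averaged", {
  # triangle wave in flexion with a value series equal to flexion
  s <- data.frame(phase = c(0, 30, 60, 90, 60, 30, 0), v = c(0, 1, 2, 3, 2, 1, 0))
  out <- resample_to_phase(s, grid = c(0, 45, 90), axis = "flexion_angle")
  expect_equal(out$v, c(0, 1.5, 3))
  # asymmetric limbs average
  s$v <- c(0, 1, 2, 3, 4, 5, 6)
  out <- resample_to_phase(s, grid = c(0, 90), axis = "flexion_angle")
  expect_equal(out$v, c((0 + 6) / 2, (3 + 3) / 2))
})
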