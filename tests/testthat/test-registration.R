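test_that("ICP of a mesh onto itself returns the identity immediately", {
  fem <- make_femoral_component(24, 11, mesh_resolution = 12)
  res <- icp_align(fem, fem)
  expect_lt(res$residual_rms, 1e-12)
  expect_lt(max(abs(res$pose$R - diag(3))), 1e-12)
  expect_true(res$converged)
})

test_that("ICP recovers a known rigid transform to high precision", {
  fem <- make_femoral_component(24, 11, mesh_resolution = 14,
                                arc_offset = -25)
  truth <- pose_from_params(c(0, 10, 0, 5, 0, 0))   # 10 deg, 5 mm
  tgt <- transform_mesh(fem, truth)
  res <- icp_align(fem, tgt)
  expect_lt(max(abs(pose_params(res$pose) - pose_params(truth))), 1e-6)
  # per-iteration residual is non-increasing
  expect_true(all(diff(res$residual_history) <= 1e-9))
})

test_that("trimming rejects a displaced outlier patch", {
  fem <- make_femoral_component(24, 11, mesh_resolution = 14)
  tgt <- fem
  out <- fem$vertices[1:floor(nrow(fem$vertices) * 0.1), , drop = FALSE]
  out[, 3] <- out[, 3] - 10
  src <- rbind(fem$vertices, out)
  res_t <- icp_align(src, tgt, trim_fraction = 0.15)
  res_u <- icp_align(src, tgt, trim_fraction = 0)
  expect_lt(res_t$residual_rms, res_u$residual_rms)
})

test_that("ICP input validation", {
  fem <- make_femoral_component(24, 11, mesh_resolution = 12)
  expect_error(icp_align(fem$vertices[1:50, ], fem), "100")
  expect_error(icp_align(fem, fem, trim_fraction = 0.7), "trim_fraction")
})

test_that("surface deviation matches a uniform plane offset and the half-normal closed form", {
  a <- plane_grid_mesh(12, 12, width = 20)
  expect_equal(unname(surface_deviation(a, a)), c(0, 0), tolerance = 1e-12)
  b <- plane_grid_mesh(40, 40, width = 30, z0 = 0.30)
  dev <- surface_deviation(a, b)
  expect_equal(unname(dev), c(0.30, 0), tolerance = 1e-9)
  # |N(0, 0.2)| offsets along the normal: mean is sigma * sqrt(2/pi)
  set.seed(21)
  pert <- a
  pert$vertices[, 3] <- abs(rnorm(nrow(a$vertices), 0, 0.2))
  dev <- surface_deviation(pert, b <- plane_grid_mesh(50, 50, width = 40))
  expect_equal(dev[["mean"]], 0.2 * sqrt(2 / pi), tolerance = 0.02)
})

test_that("silhouette pose estimation is exact for contours synthesized at the initial pose", {
  fem <- make_femoral_component(24, 11, mesh_resolution = 14,
                                arc_offset = -25)
  cams <- dfis_camera_pair()
  truth <- pose_from_params(c(4, -6, 3, 2, -1, 3))
  cts <- lapply(cams, function(cm) project_silhouette(fem, truth, cm, 80))
  res <- estimate_pose_dfis(fem, cts, cams, truth)
  expect_lt(res$residual_rms, 1e-6)
  expect_lt(max(abs(pose_params(res$pose) - pose_params(truth))), 1e-4)
  expect_true(res$converged)
})

test_that("a single view is refused (depth unconstrained)", {
  fem <- make_femoral_component(24, 11, mesh_resolution = 12)
  cams <- dfis_camera_pair()
  ct <- project_silhouette(fem, rigid_pose(), cams[[1]], 60)
  expect_error(estimate_pose_dfis(fem, list(ct), cams[1], rigid_pose()),
               "two views")
})

test_that("noise-free cost is minimal at the true pose on a perturbation grid", {
  fem <- make_femoral_component(24, 11, mesh_resolution = 12,
                                arc_offset = -25)
  cams <- dfis_camera_pair()
  truth <- pose_from_params(c(2, 5, -3, 1, 2, -2))
  cts <- lapply(cams, function(cm) project_silhouette(fem, truth, cm, 60))
  topo <- ukacontact:::mesh_edge_topology(fem)
  cost <- function(par) {
    pose <- pose_from_params(par)
    sum(vapply(seq_along(cams), function(k) {
      seg <- ukacontact:::projected_silhouette_segments(fem, pose,
                                                        cams[[k]], topo)
      sum(ukacontact:::point_segment_min_d2(cts[[k]]$points, seg$a, seg$b))
    }, 0))
  }
  c0 <- cost(pose_params(truth))
  expect_lt(c0, 1e-16)
  for (j in 1:6) for (s in c(-1, 1)) {
    par <- pose_params(truth)
    par[j] <- par[j] + s * (if (j <= 3) 1 else 1)
    expect_gt(cost(par), c0)
  }
})

test_that("pose estimation is equivariant under a global rigid motion of scene and cameras", {
  fem <- make_femoral_component(24, 11, mesh_resolution = 12,
                                arc_offset = -25)
  cams <- dfis_camera_pair()
  truth <- pose_from_params(c(3, -4, 2, 1, 2, -1))
  cts <- lapply(cams, function(cm) project_silhouette(fem, truth, cm, 70))
  G <- pose_from_params(c(10, 20, -15, 30, -40, 25))
  move_cam <- function(cm) {
    cm$source <- pose_apply(G, cm$source)
    cm$center <- pose_apply(G, cm$center)
    cm$u <- as.numeric(G$R %*% cm$u)
    cm$v <- as.numeric(G$R %*% cm$v)
    cm$n <- as.numeric(G$R %*% cm$n)
    cm
  }
  cams_g <- lapply(cams, move_cam)
  truth_g <- pose_compose(G, truth)
  # identical contours in detector coordinates
  cts_g <- lapply(seq_along(cams), function(k)
    project_silhouette(fem, truth_g, cams_g[[k]], 70))
  expect_equal(cts_g[[1]]$points, cts[[1]]$points, tolerance = 1e-9)
  res <- estimate_pose_dfis(fem, cts, cams_g, truth_g)
  expect_lt(max(abs(pose_params(res$pose) - pose_params(truth_g))), 1e-4)
})
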