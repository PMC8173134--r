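test_that("sphere over a flat insert gives the closed-form contact", {
  ins <- make_tibial_insert(43, 26.5, thickness = 8, mesh_resolution = 32)
  sph <- make_femoral_component(20, 20, arc_span = 180,
                                mesh_resolution = 40)
  # center at (3, -2), lowest point 0.5 mm above the superior surface
  pose <- rigid_pose(translation = c(3, -2, 8 + 20.5))
  rec <- closest_point_contact(transform_mesh(sph, pose,
                                              "tibial_component"), ins)
  expect_equal(rec$ap, 3, tolerance = 0.05)
  expect_equal(rec$ml, -2, tolerance = 0.05)
  expect_equal(rec$gap, 0.5, tolerance = 1e-3)
  expect_false(rec$no_contact)
  # touching sphere: gap 0
  pose <- rigid_pose(translation = c(3, -2, 8 + 20))
  rec <- closest_point_contact(transform_mesh(sph, pose,
                                              "tibial_component"), ins)
  expect_equal(rec$gap, 0, tolerance = 1e-6)
  expect_equal(c(rec$ap, rec$ml), c(3, -2), tolerance = 0.05)
})

test_that("accelerated contact equals the independent exhaustive oracle on a dished insert", {
  ins <- make_tibial_insert(30, 22, dish_radius = 100, thickness = 8,
                            mesh_resolution = 10)
  sph <- make_femoral_component(20, 20, arc_span = 180,
                                mesh_resolution = 14)
  set.seed(41)
  for (i in 1:8) {
    pose <- rigid_pose(euler_to_matrix(runif(1, -5, 5),
                                       runif(1, -10, 10), 0),
                       c(runif(2, -4, 4), 8 + 20 + runif(1, 0.3, 1)))
    fem <- transform_mesh(sph, pose, "tibial_component")
    rec <- closest_point_contact(fem, ins)
    orc <- oracle_contact(fem, ins)
    expect_equal(rec$gap, orc$dist, tolerance = 1e-9)
  }
})

test_that("penetration selects the deepest point with a negative gap", {
  ins <- make_tibial_insert(43, 26.5, thickness = 8, mesh_resolution = 24)
  sph <- make_femoral_component(20, 20, arc_span = 180,
                                mesh_resolution = 30)
  pose <- rigid_pose(translation = c(0, 0, 8 + 20 - 0.3))  # 0.3 mm into it
  rec <- closest_point_contact(transform_mesh(sph, pose,
                                              "tibial_component"), ins)
  expect_lt(rec$gap, 0)
  expect_equal(rec$gap, -0.3, tolerance = 0.01)
  expect_equal(c(rec$ap, rec$ml), c(0, 0), tolerance = 0.1)
})

test_that("a distracted joint raises the no-contact flag", {
  ins <- make_tibial_insert(43, 26.5, thickness = 8, mesh_resolution = 16)
  sph <- make_femoral_component(20, 20, mesh_resolution = 16)
  pose <- rigid_pose(translation = c(0, 0, 8 + 20 + 10))
  rec <- closest_point_contact(transform_mesh(sph, pose,
                                              "tibial_component"), ins)
  expect_true(rec$no_contact)
})

test_that("normalization and representative-insert mapping follow their definitions", {
  rec <- contact_record(ap = 0, ml = 0, gap = 0)
  expect_equal(normalize_contact(rec, 43, 26.5)$ap_pct, 0)
  rec <- contact_record(ap = 21.5, ml = 0, gap = 0)
  expect_equal(normalize_contact(rec, 43, 26.5)$ap_pct, 50)
  # the reported sit-to-stand AP average: 2.1 mm on 43 mm -> 4.9%
  rec <- contact_record(ap = 2.1, ml = 0, gap = 0)
  expect_equal(round(normalize_contact(rec, 43, 26.5)$ap_pct, 1), 4.9)
  # ML normalization uses the width: 1.8 mm on 26.5 mm -> 6.8%
  rec <- contact_record(ap = 0, ml = 1.8, gap = 0)
  expect_equal(round(normalize_contact(rec, 43, 26.5)$ml_pct, 1), 6.8)
  # mapping preserves percentages exactly, identity at equal dimensions
  rec <- contact_record(ap = 5, ml = 1, gap = 0)
  m1 <- map_to_representative(rec, 43, 26.5)
  expect_equal(c(m1$ap, m1$ml), c(5, 1), tolerance = 1e-12)
  m2 <- map_to_representative(rec, 50, 30)
  expect_equal(m2$ap_pct, 5 / 50 * 100, tolerance = 1e-12)
  expect_equal(m2$ap, 5 / 50 * 43, tolerance = 1e-12)
  # the in vitro center at -1.1% maps to about -0.5 mm on the 43-mm insert
  lit <- contact_record(ap = -1.1, ml = 0, gap = 0)   # on a 100-mm insert
  m3 <- map_to_representative(lit, 100, 100)
  expect_equal(round(m3$ap, 1), -0.5)
  expect_equal(m3$ap, -0.473, tolerance = 1e-3)
})

test_that("normalize / map / de-normalize round-trips in percent space", {
  rec <- contact_record(ap = 4.2, ml = -1.3, gap = 0)
  a <- normalize_contact(rec, 40, 24)
  b <- map_to_representative(a, 40, 24, rep_length = 43, rep_width = 26.5)
  c2 <- normalize_contact(b, 43, 26.5)
  expect_equal(c2$ap_pct, a$ap_pct, tolerance = 1e-12)
  expect_equal(c2$ml_pct, a$ml_pct, tolerance = 1e-12)
})

test_that("excursion summary reproduces hand arithmetic", {
  tr <- data.frame(ap = c(3, 5, 7), ml = c(1, 1, 1))
  s <- excursion_summary(list(tr))
  expect_equal(s$per_trial$ap_avg, 5)
  expect_equal(s$per_trial$ap_range, 4)
  expect_equal(s$per_trial$ml_range, 0)
  # two subjects with per-trial averages 4 and 6 -> 5 +/- sqrt(2)
  t1 <- data.frame(ap = c(3, 5), ml = c(0, 0))
  t2 <- data.frame(ap = c(5, 7), ml = c(0, 0))
  s <- excursion_summary(list(t1, t2))
  expect_equal(s$stats$mean[s$stats$quantity == "ap_avg"], 5)
  expect_equal(s$stats$sd[s$stats$quantity == "ap_avg"], sqrt(2),
               tolerance = 1e-12)
  expect_warning(excursion_summary(list(t1, data.frame())), "skipped")
})

test_that("offsets versus the in vitro reference center reproduce the published values", {
  tab <- invivo_contact_table()
  ref <- wear_reference_center()
  off <- offset_vs_reference(tab$ap_avg_mean, tab$ml_avg_mean, ref)
  expect_equal(round(off$per_subject$ap_offset, 1), c(5.7, 1.5, 2.6))
  expect_equal(round(off$per_subject$ml_offset, 1), c(1.1, 0.2, 0.7))
  # coordinate equal to the reference gives zero offset
  z <- offset_vs_reference(ref$ap_mm, ref$ml_mm, ref)
  expect_equal(unname(unlist(z$per_subject)), c(0, 0))
})
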