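test_that("femoral component is watertight, consistently wound and lies on the analytic torus", {
  fem <- make_femoral_component(22, 18, arc_span = 120, mesh_resolution = 16)
  expect_true(is_watertight(fem))
  expect_true(check_winding(fem))
  a <- 22 - 18
  av <- fem$vertices[fem$articular, ]
  residual <- (sqrt(av[, 1]^2 + av[, 3]^2) - a)^2 + av[, 2]^2 - 18^2
  expect_lt(max(abs(residual)), 1e-6)
})

test_that("equal radii give the sphere limit: all articular vertices at the sphere radius", {
  sph <- make_femoral_component(20, 20, arc_span = 180, mesh_resolution = 16)
  expect_true(is_watertight(sph))
  d <- sqrt(rowSums(sph$vertices[sph$articular, ]^2))
  expect_lt(max(abs(d - 20)), 1e-9)
})

test_that("doubling the mesh resolution reduces the chord deviation from the analytic torus", {
  dev_at <- function(res) {
    fem <- make_femoral_component(22, 18, arc_span = 120,
                                  mesh_resolution = res)
    f <- fem$faces[apply(matrix(fem$articular[fem$faces], ncol = 3), 1,
                         all), , drop = FALSE]
    cent <- (fem$vertices[f[, 1], ] + fem$vertices[f[, 2], ] +
               fem$vertices[f[, 3], ]) / 3
    a <- 22 - 18
    max(abs(sqrt((sqrt(cent[, 1]^2 + cent[, 3]^2) - a)^2 + cent[, 2]^2) - 18))
  }
  d1 <- dev_at(10); d2 <- dev_at(20)
  expect_lt(d2, d1)
  expect_lt(d2, d1 / 2)  # quadratic convergence of chord error
})

test_that("femoral parameter validation catches bad inputs", {
  expect_error(make_femoral_component(-1, 10), "positive")
  expect_error(make_femoral_component(20, 10, mesh_resolution = 4), "resolution")
  expect_error(make_femoral_component(20, 10, arc_span = 60), "arc_span")
})

test_that("flat insert superior surface sits exactly at the thickness", {
  ins <- make_tibial_insert(43, 26.5, thickness = 8, mesh_resolution = 12)
  expect_true(is_watertight(ins))
  expect_true(check_winding(ins))
  top_v <- unique(as.vector(ins$faces[ins$superior_faces, ]))
  expect_lt(max(abs(ins$vertices[top_v, 3] - 8)), 1e-12)
  expect_equal(ins$centroid, c(0, 0, 8))
})

test_that("a very large dish radius converges to the flat insert", {
  flat <- make_tibial_insert(43, 26.5, mesh_resolution = 12)
  near <- make_tibial_insert(43, 26.5, dish_radius = 1e9,
                             mesh_resolution = 12)
  expect_lt(max(abs(near$vertices - flat$vertices)), 1e-6)
})

test_that("dished superior surface follows the spherical-cap closed form", {
  ins <- make_tibial_insert(40, 26, dish_radius = 100, thickness = 8,
                            mesh_resolution = 16)
  top_v <- unique(as.vector(ins$faces[ins$superior_faces, ]))
  v <- ins$vertices[top_v, ]
  rho2 <- v[, 1]^2 + v[, 2]^2
  expect_equal(v[, 3], 8 + (100 - sqrt(100^2 - rho2)), tolerance = 1e-9)
  # lowest superior point at the footprint center
  expect_lt(min(rho2[v[, 3] == min(v[, 3])]), 1e-12)
})

test_that("insert parameter validation catches bad inputs", {
  expect_error(make_tibial_insert(0, 26.5), "positive")
  expect_error(make_tibial_insert(43, 26.5, dish_radius = -3), "positive")
  expect_error(make_tibial_insert(43, 26.5, dish_radius = 20),
               "half-diagonal")
})

test_that("implant set defaults encode the representative insert", {
  imp <- small_implants()
  expect_equal(imp$insert_length, 43)
  expect_equal(imp$insert_width, 26.5)
  expect_s3_class(imp$femoral_condyle, "surface_mesh")
  expect_true(is_watertight(imp$baseplate))
})

test_that("degenerate meshes are rejected by the constructor", {
  expect_error(surface_mesh(matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0), 3, 3,
                                   byrow = TRUE),
                            matrix(c(1, 2, 3), 1)), "degenerate")
  expect_error(surface_mesh(matrix(rnorm(9), 3), matrix(c(1, 2, 4), 1)),
               "out of range")
})
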