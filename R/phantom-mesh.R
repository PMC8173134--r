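# Synthetic implant geometry.  The femoral condyle is a toroidal-section
# proxy (coronal circular arc swept along a sagittal circular arc) closed
# into a watertight solid; the tibial insert is a block whose superior
# surface is flat or a shallow spherical dish.  Component frames follow the
# right-knee convention: x anterior(+), y medial(+), z proximal(+), mm.
# Face windings are constructed outward-consistent analytically; a signed
# volume check guards against regressions.

# Merge coincident vertices (within tol) and drop zero-area faces; needed in
# the sphere limit where the sagittal spine collapses to a point.
weld_mesh <- function(vertices, faces, tol = 1e-9) {
  key <- paste(round(vertices[, 1] / tol), round(vertices[, 2] / tol),
               round(vertices[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])          # old vertex -> new vertex id
  vertices <- vertices[first, , drop = FALSE]
  faces <- matrix(map[faces], ncol = 3)
  keep <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
    faces[, 1] != faces[, 3]
  faces <- faces[keep, , drop = FALSE]
  keep2 <- face_areas(vertices, faces) > 1e-12
  list(vertices = vertices, faces = faces[keep2, , drop = FALSE],
       vertex_map = map)
}

signed_volume <- function(vertices, faces) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  sum(v1[, 1] * (v2[, 2] * v3[, 3] - v3[, 2] * v2[, 3]) -
      v2[, 1] * (v1[, 2] * v3[, 3] - v3[, 2] * v1[, 3]) +
      v3[, 1] * (v1[, 2] * v2[, 3] - v2[, 2] * v1[, 3])) / 6
}

#' Check outward-consistent winding
#'
#' A closed mesh is consistently wound when every undirected edge is
#' traversed once in each direction by its two adjacent faces.
#'
#' @param mesh a [surface_mesh()].
#' @return `TRUE` if the winding is consistent (and the mesh closed).
#' @export
check_winding <- function(mesh) {
  f <- mesh$faces
  dkey <- c(paste(f[, 1], f[, 2]), paste(f[, 2], f[, 3]),
            paste(f[, 3], f[, 1]))
  rkey <- c(paste(f[, 2], f[, 1]), paste(f[, 3], f[, 2]),
            paste(f[, 1], f[, 3]))
  !anyDuplicated(dkey) && all(dkey %in% rkey)
}

#' Synthetic femoral condyle component
#'
#' A toroidal-section articular surface: a coronal circular arc of radius
#' `coronal_radius` swept along a sagittal circular arc of radius
#' `sagittal_radius`, closed into a watertight solid by a central fin to
#' the sagittal spine.  The torus axis is the medial-lateral (y) axis; the
#' articular band faces distally (-z).  In the sphere limit (equal radii)
#' the articular band lies on a sphere of that radius.
#'
#' @param sagittal_radius sagittal articular radius (mm).
#' @param coronal_radius coronal articular radius (mm); must not exceed
#'   `sagittal_radius`.
#' @param arc_span sagittal arc span in degrees, between 90 and 180.
#' @param mesh_resolution coronal grid divisions; >= 8.  The sagittal
#'   division count scales with `arc_span`.
#' @param arc_offset rotates the arc center away from straight-down
#'   (degrees, negative = posterior); lets deep-flexion motion keep the
#'   contact on the articular band.
#' @param coronal_span half-band of the coronal arc (degrees), default 60.
#' @return A [surface_mesh()] with `articular` flagging the bearing-band
#'   vertices and the generating radii stored as fields.
#' @export
make_femoral_component <- function(sagittal_radius, coronal_radius,
                                   arc_span = 150, mesh_resolution = 32,
                                   arc_offset = 0, coronal_span = 60) {
  if (sagittal_radius <= 0 || coronal_radius <= 0)
    stop("make_femoral_component: radii must be positive")
  if (mesh_resolution < 8) stop("make_femoral_component: resolution < 8")
  if (arc_span < 90 || arc_span > 180)
    stop("make_femoral_component: arc_span must be in [90, 180] degrees")
  if (coronal_radius > sagittal_radius + 1e-9)
    stop("make_femoral_component: coronal_radius must be <= sagittal_radius")
  a <- sagittal_radius - coronal_radius
  rc <- coronal_radius
  n_phi <- as.integer(mesh_resolution)
  n_th <- max(8L, as.integer(round(mesh_resolution * arc_span / 90)))
  th <- (arc_offset + seq(-arc_span / 2, arc_span / 2,
                          length.out = n_th + 1)) * pi / 180
  ph <- seq(-coronal_span, coronal_span, length.out = n_phi + 1) * pi / 180
  u <- cbind(sin(th), 0, -cos(th))               # sagittal radial direction
  nt <- n_th + 1L
  np <- n_phi + 1L
  idx <- function(i, j) (j - 1L) * nt + i        # band grid vertex ids
  V <- matrix(0, nt * np, 3)
  for (j in seq_len(np)) {
    r <- a + rc * cos(ph[j])
    V[idx(seq_len(nt), j), ] <- cbind(r * u[, 1], rc * sin(ph[j]), r * u[, 3])
  }
  spine <- u * a                                 # arc of tube centers
  V <- rbind(V, spine)
  sid <- nt * np + seq_len(nt)
  F <- vector("list", 0)
  # band: cross(T_phi, T_theta) is outward -> tris (A, D, C), (A, C, B)
  for (i in seq_len(n_th)) for (j in seq_len(n_phi)) {
    A <- idx(i, j); B <- idx(i + 1L, j)
    C <- idx(i + 1L, j + 1L); D <- idx(i, j + 1L)
    F[[length(F) + 1L]] <- rbind(c(A, D, C), c(A, C, B))
  }
  # fin walls: -phi side winds band->spine one way, +phi side the other
  for (i in seq_len(n_th)) {
    A <- idx(i, 1L); B <- idx(i + 1L, 1L)
    F[[length(F) + 1L]] <- rbind(c(A, B, sid[i + 1L]), c(A, sid[i + 1L], sid[i]))
    A <- idx(i, np); B <- idx(i + 1L, np)
    F[[length(F) + 1L]] <- rbind(c(A, sid[i], sid[i + 1L]), c(A, sid[i + 1L], B))
  }
  # end fans: outward -u' at theta_min, +u' at theta_max
  for (j in seq_len(n_phi)) {
    F[[length(F) + 1L]] <- rbind(c(sid[1L], idx(1L, j + 1L), idx(1L, j)))
    F[[length(F) + 1L]] <- rbind(c(sid[nt], idx(nt, j), idx(nt, j + 1L)))
  }
  F <- do.call(rbind, F)
  art <- c(rep(TRUE, nt * np), rep(FALSE, nt))
  w <- weld_mesh(V, F, tol = 1e-9 * max(1, sagittal_radius))
  art_new <- rep(FALSE, nrow(w$vertices))
  art_new[w$vertex_map[art]] <- TRUE
  if (signed_volume(w$vertices, w$faces) < 0)
    stop("make_femoral_component: internal winding error")   # nocov
  m <- surface_mesh(w$vertices, w$faces, frame_label = "femoral_component",
                    articular = art_new)
  m$sagittal_radius <- sagittal_radius
  m$coronal_radius <- coronal_radius
  m$arc_span <- arc_span
  m$arc_offset <- arc_offset
  m$coronal_span <- coronal_span
  m
}

#' Synthetic tibial polyethylene insert (or baseplate block)
#'
#' A block of the given anterior-posterior `length` and medial-lateral
#' `width`, centered at the origin, inferior face at z = 0.  The superior
#' surface is flat at z = `thickness` or a shallow spherical dish (lowest
#' at the footprint center, rising toward the edges) when `dish_radius` is
#' finite.  The low-congruence design of the emulated implant corresponds
#' to a large `dish_radius` relative to the mating coronal radius.
#'
#' @param length AP extent (mm); default 43 (representative insert).
#' @param width ML extent (mm); default 26.5.
#' @param dish_radius superior dish radius (mm) or `Inf` for flat.
#' @param thickness height of the superior surface at the footprint
#'   center (mm).
#' @param mesh_resolution AP grid divisions; >= 8.
#' @return A [surface_mesh()] carrying `length`, `width`, `thickness`,
#'   `dish_radius`, `centroid` (superior-surface centroid) and
#'   `superior_faces` (row indices of superior-surface faces).
#' @export
make_tibial_insert <- function(length = 43, width = 26.5, dish_radius = Inf,
                               thickness = 8, mesh_resolution = 24) {
  if (length <= 0 || width <= 0 || thickness <= 0)
    stop("make_tibial_insert: dimensions must be positive")
  if (!is.infinite(dish_radius) && dish_radius <= 0)
    stop("make_tibial_insert: dish_radius must be positive or Inf")
  half_diag <- sqrt((length / 2)^2 + (width / 2)^2)
  if (!is.infinite(dish_radius) && dish_radius <= half_diag)
    stop("make_tibial_insert: dish_radius must exceed the half-diagonal")
  nx <- max(8L, as.integer(mesh_resolution))
  ny <- max(6L, as.integer(round(mesh_resolution * width / length)))
  xs <- seq(-length / 2, length / 2, length.out = nx + 1)
  ys <- seq(-width / 2, width / 2, length.out = ny + 1)
  g <- expand.grid(x = xs, y = ys)
  topz <- if (is.infinite(dish_radius)) rep(thickness, nrow(g)) else
    thickness + (dish_radius - sqrt(dish_radius^2 - g$x^2 - g$y^2))
  ntop <- nrow(g)
  V <- rbind(cbind(g$x, g$y, topz), cbind(g$x, g$y, 0))
  idx <- function(i, j) (j - 1L) * (nx + 1L) + i          # top grid
  bid <- function(i, j) ntop + idx(i, j)                  # bottom grid
  F <- vector("list", 0)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    A <- idx(i, j); B <- idx(i + 1L, j)
    C <- idx(i + 1L, j + 1L); D <- idx(i, j + 1L)
    F[[length(F) + 1L]] <- rbind(c(A, B, C), c(A, C, D))      # top, +z out
    A <- bid(i, j); B <- bid(i + 1L, j)
    C <- bid(i + 1L, j + 1L); D <- bid(i, j + 1L)
    F[[length(F) + 1L]] <- rbind(c(A, D, C), c(A, C, B))      # bottom, -z out
  }
  for (i in seq_len(nx)) {                                    # y walls
    A <- idx(i, 1L); B <- idx(i + 1L, 1L)
    Ab <- bid(i, 1L); Bb <- bid(i + 1L, 1L)
    F[[length(F) + 1L]] <- rbind(c(A, Ab, Bb), c(A, Bb, B))   # -y out
    A <- idx(i, ny + 1L); B <- idx(i + 1L, ny + 1L)
    Ab <- bid(i, ny + 1L); Bb <- bid(i + 1L, ny + 1L)
    F[[length(F) + 1L]] <- rbind(c(A, B, Bb), c(A, Bb, Ab))   # +y out
  }
  for (j in seq_len(ny)) {                                    # x walls
    A <- idx(1L, j); B <- idx(1L, j + 1L)
    Ab <- bid(1L, j); Bb <- bid(1L, j + 1L)
    F[[length(F) + 1L]] <- rbind(c(A, B, Bb), c(A, Bb, Ab))   # -x out
    A <- idx(nx + 1L, j); B <- idx(nx + 1L, j + 1L)
    Ab <- bid(nx + 1L, j); Bb <- bid(nx + 1L, j + 1L)
    F[[length(F) + 1L]] <- rbind(c(A, Ab, Bb), c(A, Bb, B))   # +x out
  }
  F <- do.call(rbind, F)
  if (signed_volume(V, F) < 0)
    stop("make_tibial_insert: internal winding error")        # nocov
  m <- surface_mesh(V, F, frame_label = "tibial_component")
  # superior faces are exactly those using top-grid vertices only
  m$superior_faces <- which(apply(matrix(F %in% seq_len(ntop), ncol = 3),
                                  1, all))
  m$length <- length
  m$width <- width
  m$thickness <- thickness
  m$dish_radius <- dish_radius
  m$centroid <- c(0, 0, mean(topz))
  m
}

#' Assemble the synthetic implant set
#'
#' @param femoral_condyle,insert,baseplate [surface_mesh()] components; any
#'   omitted component is built with the defaults.
#' @param insert_length,insert_width insert footprint (mm); defaults 43 and
#'   26.5 (representative insert).
#' @param sagittal_radius,coronal_radius femoral articular radii (mm).
#' @param dish_radius insert superior dish radius (mm), `Inf` = flat
#'   (low-congruence default).
#' @param femoral_resolution,insert_resolution mesh resolutions.
#' @param arc_span,arc_offset femoral sagittal arc parameters (degrees).
#' @return List of class `implant_set` with the three components and the
#'   insert dimensions/centroid.
#' @export
implant_set <- function(femoral_condyle = NULL, insert = NULL,
                        baseplate = NULL, insert_length = 43,
                        insert_width = 26.5, sagittal_radius = 24,
                        coronal_radius = 11, dish_radius = Inf,
                        femoral_resolution = 32, insert_resolution = 24,
                        arc_span = 150, arc_offset = -25) {
  if (is.null(femoral_condyle))
    femoral_condyle <- make_femoral_component(
      sagittal_radius, coronal_radius, arc_span = arc_span,
      mesh_resolution = femoral_resolution, arc_offset = arc_offset)
  if (is.null(insert))
    insert <- make_tibial_insert(insert_length, insert_width,
                                 dish_radius = dish_radius,
                                 mesh_resolution = insert_resolution)
  if (is.null(baseplate)) {
    baseplate <- make_tibial_insert(insert$length + 2, insert$width + 2,
                                    dish_radius = Inf, thickness = 3,
                                    mesh_resolution = 12)
    baseplate$vertices[, 3] <- baseplate$vertices[, 3] - 3    # top at z = 0
    baseplate$centroid <- baseplate$centroid - c(0, 0, 3)
    baseplate$frame_label <- "tibial_component"
  }
  structure(list(femoral_condyle = femoral_condyle, insert = insert,
                 baseplate = baseplate, insert_length = insert$length,
                 insert_width = insert$width,
                 insert_centroid = insert$centroid),
            class = "implant_set")
}

#' @export
print.implant_set <- function(x, ...) {
  cat(sprintf(
    "<implant_set> insert %.1f x %.1f mm; femoral %d faces, insert %d faces\n",
    x$insert_length, x$insert_width, nrow(x$femoral_condyle$faces),
    nrow(x$insert$faces)))
  invisible(x)
}
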