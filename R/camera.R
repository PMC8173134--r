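# Virtual fluoroscope geometry: a point X-ray source and a flat detector.
# Silhouettes are formed by central projection of the occluding contour of
# a watertight mesh (edges separating source-facing from source-averted
# triangles, facing judged along the per-edge ray to the source).

#' Construct a fluoroscope camera model
#'
#' @param source_position 3-vector, X-ray point source (mm, world frame).
#' @param detector_center 3-vector, center of the detector plane (mm).
#' @param up_hint 3-vector used to fix the in-plane detector axes; must not
#'   be parallel to the viewing direction.
#' @param view_id label for the view.
#' @return Object of class `camera_model` with orthonormal in-plane axes
#'   `u`, `v`, the unit viewing direction `n`, and the source-detector
#'   distance.
#' @export
camera_model <- function(source_position, detector_center,
                         up_hint = c(0, 0, 1), view_id = "view") {
  s <- as.numeric(source_position); c0 <- as.numeric(detector_center)
  d <- c0 - s
  sdd <- sqrt(sum(d^2))
  if (sdd <= 0) stop("camera_model: source coincides with detector center")
  n <- d / sdd
  u <- pracma_cross(up_hint, n)
  if (sqrt(sum(u^2)) < 1e-9)
    stop("camera_model: up_hint parallel to viewing direction")
  u <- u / sqrt(sum(u^2))
  v <- pracma_cross(n, u)
  structure(list(source = s, center = c0, u = u, v = v, n = n,
                 source_detector_distance = sdd, view_id = view_id),
            class = "camera_model")
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Default dual-fluoroscope camera pair
#'
#' Two fluoroscopes with viewing directions separated by `angle` degrees
#' (default 90, approximately orthogonal), both aimed at the world origin.
#'
#' @param source_detector_distance mm, default 1000 (typical C-arm).
#' @param object_distance source-to-isocenter distance, default 700 mm.
#' @param angle separation of the two viewing directions (degrees),
#'   between 80 and 100.
#' @return List of two [camera_model()] objects.
#' @export
dfis_camera_pair <- function(source_detector_distance = 1000,
                             object_distance = 700, angle = 90) {
  if (angle < 80 || angle > 100)
    stop("dfis_camera_pair: views must be 80-100 degrees apart")
  mk <- function(az, id) {
    dir <- c(cos(az * pi / 180), sin(az * pi / 180), 0)
    camera_model(-object_distance * dir,
                 (source_detector_distance - object_distance) * dir,
                 view_id = id)
  }
  list(mk(0, "view1"), mk(angle, "view2"))
}

#' A 2D silhouette contour in detector coordinates
#'
#' @param points n x 2 matrix of detector-plane coordinates (mm).
#' @param view_id label of the originating view.
#' @return Object of class `contour_2d`.
#' @export
contour_2d <- function(points, view_id = "view") {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("contour_2d: points must be n x 2")
  if (nrow(points) < 20L) stop("contour_2d: at least 20 points required")
  if (!all(is.finite(points))) stop("contour_2d: non-finite point")
  structure(list(view_id = view_id, points = points), class = "contour_2d")
}

# Central projection of world points onto the detector plane.
# Returns n x 2 matrix of (u, v) coordinates in mm.
project_points <- function(points, camera) {
  if (is.null(dim(points))) points <- matrix(points, 1)
  rel <- sweep(points, 2, camera$source)          # rays from source
  denom <- rel %*% camera$n
  if (any(denom <= 1e-9))
    stop("silhouette projection: geometry error (point behind source)")
  scale <- as.numeric(camera$source_detector_distance / denom)
  hit <- rel * scale + matrix(camera$source, nrow(rel), 3, byrow = TRUE)
  rel_c <- sweep(hit, 2, camera$center)
  cbind(rel_c %*% camera$u, rel_c %*% camera$v)
}

# Occluding-contour edges of a mesh (world-frame vertices) as seen from the
# camera source.  topo may be precomputed with mesh_edge_topology().
# Returns k x 4 matrix of vertex index pairs' endpoints? No: returns list
# with 3D segment endpoints (k x 3 each).
silhouette_edges <- function(vertices, faces, camera,
                             topo = NULL) {
  if (is.null(topo))
    topo <- mesh_edge_topology(surface_mesh(vertices, faces,
                                            validate = FALSE))
  if (anyNA(topo$face2))
    stop("silhouette_edges: mesh is not closed")
  n <- face_normals(vertices, faces)
  e1 <- topo$edges[, 1]; e2 <- topo$edges[, 2]
  mid <- (vertices[e1, , drop = FALSE] + vertices[e2, , drop = FALSE]) / 2
  ray <- sweep(-mid, 2, camera$source, "+")       # edge midpoint -> source
  f1 <- rowSums(n[topo$face1, , drop = FALSE] * ray) > 0
  f2 <- rowSums(n[topo$face2, , drop = FALSE] * ray) > 0
  sil <- which(xor(f1, f2))
  if (!length(sil)) stop("silhouette_edges: no occluding contour found")
  list(p1 = vertices[e1[sil], , drop = FALSE],
       p2 = vertices[e2[sil], , drop = FALSE])
}

# Projected silhouette of a mesh at a pose: 2D segments on the detector.
# Used both for contour synthesis and for the registration cost.
projected_silhouette_segments <- function(mesh, pose, camera, topo = NULL) {
  v <- pose_apply(pose, mesh$vertices)
  se <- silhouette_edges(v, mesh$faces, camera, topo)
  list(a = project_points(se$p1, camera), b = project_points(se$p2, camera))
}

#' Project the occluding contour of a mesh onto a fluoroscope detector
#'
#' Extracts the occluding contour of the posed mesh (edges whose two
#' adjacent triangles face oppositely with respect to the per-edge ray to
#' the source) and samples it, proportionally to edge length, to
#' `n_samples` points centrally projected onto the detector plane.
#'
#' @param mesh a watertight [surface_mesh()].
#' @param pose the [rigid_pose()] of the mesh in world coordinates.
#' @param camera a [camera_model()].
#' @param n_samples number of contour points to return (>= 20).
#' @return A [contour_2d()].
#' @export
project_silhouette <- function(mesh, pose, camera, n_samples = 150) {
  if (n_samples < 20) stop("project_silhouette: n_samples must be >= 20")
  v <- pose_apply(pose, mesh$vertices)
  rel <- sweep(v, 2, camera$source)
  if (any(rel %*% camera$n <= 0))
    stop("project_silhouette: mesh behind or intersecting the source")
  seg <- projected_silhouette_segments(mesh, pose, camera)
  len <- sqrt(rowSums((seg$b - seg$a)^2))
  cum <- cumsum(len)
  total <- cum[length(cum)]
  # arc-length positions of the samples along the concatenated segments
  s <- (seq_len(n_samples) - 0.5) / n_samples * total
  sid <- findInterval(s, c(0, cum), rightmost.closed = TRUE)
  sid <- pmin(pmax(sid, 1L), length(len))
  t0 <- (s - c(0, cum)[sid]) / pmax(len[sid], 1e-300)
  pts <- seg$a[sid, , drop = FALSE] +
    (seg$b[sid, , drop = FALSE] - seg$a[sid, , drop = FALSE]) * t0
  contour_2d(pts, view_id = camera$view_id)
}
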