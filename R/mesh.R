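# Triangulated surface meshes.  Vertices are an n x 3 matrix in mm; faces an
# m x 3 integer matrix of 1-based vertex indices with outward-consistent
# winding (right-hand rule normals point out of the solid).

#' Construct a triangulated surface mesh
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices; winding must
#'   be consistent (outward normals) for silhouette extraction.
#' @param frame_label character label of the coordinate frame the vertices
#'   are expressed in.
#' @param articular optional logical vector (length n) flagging vertices on
#'   the articular bearing surface; used by the contact search.
#' @param validate check invariants (finite coordinates, indices in range,
#'   no zero-area faces). Default `TRUE`.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, frame_label = "component",
                         articular = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("surface_mesh: vertices and faces must have 3 columns")
  if (validate) {
    if (!all(is.finite(vertices))) stop("surface_mesh: non-finite vertex")
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("surface_mesh: face index out of range")
    if (any(face_areas(vertices, faces) <= 1e-12))
      stop("surface_mesh: degenerate (zero-area) face")
  }
  m <- structure(list(vertices = vertices, faces = faces,
                      frame_label = frame_label, articular = articular),
                 class = "surface_mesh")
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, frame '%s'\n",
              nrow(x$vertices), nrow(x$faces), x$frame_label))
  invisible(x)
}

face_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Per-face unit normals
#' @param mesh a [surface_mesh()], or an n x 3 vertex matrix if `faces` given.
#' @param faces optional face matrix when `mesh` is a vertex matrix.
#' @return m x 3 matrix of unit normals (right-hand rule).
#' @export
face_normals <- function(mesh, faces = NULL) {
  if (inherits(mesh, "surface_mesh")) {
    v <- mesh$vertices; f <- mesh$faces
  } else {
    v <- mesh; f <- faces
  }
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / sqrt(rowSums(n^2))
}

#' Rigidly transform a mesh
#'
#' @param mesh a [surface_mesh()].
#' @param pose a [rigid_pose()].
#' @param frame_label label for the destination frame.
#' @return The transformed [surface_mesh()].
#' @export
transform_mesh <- function(mesh, pose, frame_label = "world") {
  out <- mesh
  out$vertices <- pose_apply(pose, mesh$vertices)
  out$frame_label <- frame_label
  out
}

#' Edge topology of a mesh
#'
#' Returns the unique undirected edges with their one or two adjacent faces;
#' used by silhouette extraction and the watertightness check.  The result
#' can be cached and reused across rigid transforms of the same mesh.
#'
#' @param mesh a [surface_mesh()].
#' @return List with `edges` (k x 2 vertex indices), `face1`, `face2`
#'   (adjacent face indices, `NA` for boundary edges).
#' @export
mesh_edge_topology <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  ea <- c(f[, 1], f[, 2], f[, 3])
  eb <- c(f[, 2], f[, 3], f[, 1])
  fid <- rep.int(seq_len(m), 3L)
  lo <- pmin(ea, eb); hi <- pmax(ea, eb)
  key <- paste(lo, hi)
  ord <- order(key)
  key <- key[ord]; lo <- lo[ord]; hi <- hi[ord]; fid <- fid[ord]
  first <- !duplicated(key)
  idx <- cumsum(first)
  k <- max(idx)
  face1 <- rep(NA_integer_, k); face2 <- rep(NA_integer_, k)
  count <- tabulate(idx, k)
  if (any(count > 2L)) stop("mesh_edge_topology: non-manifold edge")
  face1[idx[first]] <- fid[first]
  second <- !first
  face2[idx[second]] <- fid[second]
  list(edges = cbind(lo[first], hi[first]), face1 = face1, face2 = face2)
}

#' Is a mesh watertight (closed, 2-manifold)?
#' @param mesh a [surface_mesh()].
#' @return `TRUE` when every edge is shared by exactly two faces.
#' @export
is_watertight <- function(mesh) {
  topo <- tryCatch(mesh_edge_topology(mesh), error = function(e) NULL)
  !is.null(topo) && !anyNA(topo$face2)
}

# ---- point-to-triangle distances -------------------------------------------

# Closest points on many triangles to a single query point p.
# Projection onto the triangle plane; if the projection's barycentric
# coordinates leave the simplex, the closest point lies on an edge, so clamp
# via the three point-to-segment problems.  Vectorized over triangles.
# Returns list(dist, foot (k x 3)).
closest_on_triangles <- function(p, v1, v2, v3) {
  e0 <- v2 - v1
  e1 <- v3 - v1
  w <- matrix(p, nrow(v1), 3, byrow = TRUE) - v1
  a <- rowSums(e0 * e0); b <- rowSums(e0 * e1); c2 <- rowSums(e1 * e1)
  d0 <- rowSums(e0 * w); d1 <- rowSums(e1 * w)
  det <- pmax(a * c2 - b * b, 1e-300)
  s <- (c2 * d0 - b * d1) / det
  t <- (a * d1 - b * d0) / det
  inside <- s >= 0 & t >= 0 & (s + t) <= 1
  foot <- v1 + e0 * s + e1 * t
  out <- which(!inside)
  if (length(out)) {
    seg_foot <- function(p0, d, w0) {
      # p0 + clamp(t) d, t = <w0, d>/<d, d>
      tt <- rowSums(w0 * d) / pmax(rowSums(d * d), 1e-300)
      tt <- pmin(pmax(tt, 0), 1)
      p0 + d * tt
    }
    v1o <- v1[out, , drop = FALSE]; v2o <- v2[out, , drop = FALSE]
    v3o <- v3[out, , drop = FALSE]
    pm <- matrix(p, length(out), 3, byrow = TRUE)
    f1 <- seg_foot(v1o, v2o - v1o, pm - v1o)
    f2 <- seg_foot(v2o, v3o - v2o, pm - v2o)
    f3 <- seg_foot(v1o, v3o - v1o, pm - v1o)
    d1s <- rowSums((pm - f1)^2)
    d2s <- rowSums((pm - f2)^2)
    d3s <- rowSums((pm - f3)^2)
    best <- cbind(d1s, d2s, d3s)
    pick <- max.col(-best, ties.method = "first")
    fo <- f1
    fo[pick == 2L, ] <- f2[pick == 2L, , drop = FALSE]
    fo[pick == 3L, ] <- f3[pick == 3L, , drop = FALSE]
    foot[out, ] <- fo
  }
  dp <- matrix(p, nrow(v1), 3, byrow = TRUE) - foot
  list(dist = sqrt(rowSums(dp * dp)), foot = foot)
}

# Distance from each point (rows of pts) to the nearest triangle of the mesh,
# with exact vertex-distance pruning.  Returns list(dist, face, foot).
points_to_mesh_distance <- function(pts, mesh, faces_subset = NULL) {
  f <- if (is.null(faces_subset)) mesh$faces else
    mesh$faces[faces_subset, , drop = FALSE]
  v <- mesh$vertices
  v1 <- v[f[, 1], , drop = FALSE]
  v2 <- v[f[, 2], , drop = FALSE]
  v3 <- v[f[, 3], , drop = FALSE]
  # triangle "reach": max distance from first vertex to any point of the tri
  reach <- sqrt(pmax(rowSums((v2 - v1)^2), rowSums((v3 - v1)^2)))
  n <- nrow(pts)
  dist <- numeric(n); face <- integer(n); foot <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    p <- pts[i, ]
    dv <- sqrt(rowSums((v1 - matrix(p, nrow(v1), 3, byrow = TRUE))^2))
    best_upper <- min(dv)                     # distance via first vertices
    cand <- which(dv - reach <= best_upper)   # cannot beat bound otherwise
    res <- closest_on_triangles(p, v1[cand, , drop = FALSE],
                                v2[cand, , drop = FALSE],
                                v3[cand, , drop = FALSE])
    j <- which.min(res$dist)
    dist[i] <- res$dist[j]
    face[i] <- if (is.null(faces_subset)) cand[j] else faces_subset[cand[j]]
    foot[i, ] <- res$foot[j, ]
  }
  list(dist = dist, face = face, foot = foot)
}

#' Surface deviation between two meshes
#'
#' For every vertex of `mesh_a`, the unsigned distance to the nearest point
#' on the surface of `mesh_b` (point-to-triangle, not point-to-vertex);
#' summarized as mean and standard deviation.  Both meshes must be expressed
#' in the same coordinate frame.
#'
#' @param mesh_a,mesh_b [surface_mesh()] objects in a common frame.
#' @return Named numeric vector `c(mean = , sd = )` in mm.
#' @export
surface_deviation <- function(mesh_a, mesh_b) {
  if (nrow(mesh_a$vertices) == 0L || nrow(mesh_b$vertices) == 0L)
    stop("surface_deviation: empty mesh")
  d <- points_to_mesh_distance(mesh_a$vertices, mesh_b)$dist
  c(mean = mean(d), sd = stats::sd(d))
}

#' Mirror a mesh or pose across the sagittal plane
#'
#' Reflects across the plane normal to the medial-lateral (y) axis and, for
#' meshes, repairs the triangle winding so outward orientation is preserved.
#' Used to map left-knee data into the right-knee convention; applying the
#' operation twice is the identity.
#'
#' @param x a [surface_mesh()] or [rigid_pose()].
#' @return Object of the same class, mirrored.
#' @export
mirror_left_to_right <- function(x) {
  M <- diag(c(1, -1, 1))
  if (inherits(x, "surface_mesh")) {
    out <- x
    out$vertices[, 2] <- -out$vertices[, 2]
    out$faces <- out$faces[, c(1L, 3L, 2L), drop = FALSE]  # fix winding
    out
  } else if (inherits(x, "rigid_pose")) {
    rigid_pose(M %*% x$R %*% M, as.numeric(M %*% x$t))
  } else {
    stop("mirror_left_to_right: unsupported type")
  }
}
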