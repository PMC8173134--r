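# Shared fixtures and independent oracles, built in code at test time.

small_implants <- function(femoral_resolution = 16, insert_resolution = 16,
                           ...) {
  implant_set(femoral_resolution = femoral_resolution,
              insert_resolution = insert_resolution, ...)
}

# Closed full UV sphere (poles welded), for closed-form projection tests.
uv_sphere <- function(r = 15, n = 20, center = c(0, 0, 0)) {
  th <- seq(0, pi, length.out = n + 1)[2:n]        # latitudes sans poles
  ph <- seq(0, 2 * pi, length.out = 2 * n + 1)[-(2 * n + 1)]
  V <- do.call(rbind, lapply(th, function(t)
    cbind(r * sin(t) * cos(ph), r * sin(t) * sin(ph), r * cos(t))))
  np <- length(ph)
  idx <- function(i, j) (i - 1L) * np + ((j - 1L) %% np) + 1L
  F <- list()
  for (i in seq_len(n - 2)) for (j in seq_len(np)) {
    F[[length(F) + 1L]] <- rbind(
      c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
      c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  }
  top <- nrow(V) + 1L; bot <- nrow(V) + 2L
  V <- rbind(V, c(0, 0, r), c(0, 0, -r))
  for (j in seq_len(np)) {
    F[[length(F) + 1L]] <- rbind(c(top, idx(1L, j), idx(1L, j + 1L)))
    F[[length(F) + 1L]] <- rbind(c(bot, idx(n - 1L, j + 1L), idx(n - 1L, j)))
  }
  V <- sweep(V, 2, center, "+")
  surface_mesh(V, do.call(rbind, F), frame_label = "world")
}

# Open planar grid mesh in the z = z0 plane.
plane_grid_mesh <- function(nx = 10, ny = 10, width = 20, z0 = 0) {
  xs <- seq(-width / 2, width / 2, length.out = nx + 1)
  ys <- seq(-width / 2, width / 2, length.out = ny + 1)
  g <- expand.grid(x = xs, y = ys)
  idx <- function(i, j) (j - 1L) * (nx + 1L) + i
  F <- list()
  for (i in seq_len(nx)) for (j in seq_len(ny))
    F[[length(F) + 1L]] <- rbind(
      c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
      c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  surface_mesh(cbind(g$x, g$y, z0), do.call(rbind, F),
               frame_label = "world")
}

# Independent scalar point-to-triangle distance: plane projection with
# barycentric test, else the three edge-segment distances.
oracle_point_tri_dist <- function(p, a, b, c) {
  n <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
         (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
         (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
  n <- n / sqrt(sum(n^2))
  q <- p - sum((p - a) * n) * n
  # barycentric via 2x2 solve
  e0 <- b - a; e1 <- c - a; w <- q - a
  d00 <- sum(e0 * e0); d01 <- sum(e0 * e1); d11 <- sum(e1 * e1)
  d20 <- sum(w * e0); d21 <- sum(w * e1)
  den <- d00 * d11 - d01 * d01
  s <- (d11 * d20 - d01 * d21) / den
  t <- (d00 * d21 - d01 * d20) / den
  if (s >= 0 && t >= 0 && s + t <= 1) return(sqrt(sum((p - q)^2)))
  seg <- function(u, v) {
    tt <- sum((p - u) * (v - u)) / sum((v - u)^2)
    tt <- min(max(tt, 0), 1)
    sqrt(sum((p - (u + tt * (v - u)))^2))
  }
  min(seg(a, b), seg(b, c), seg(a, c))
}

# Plain double-loop exhaustive contact oracle: every femoral articular
# vertex against every insert superior triangle.
oracle_contact <- function(femoral_mesh, insert) {
  pts <- femoral_mesh$vertices
  if (!is.null(femoral_mesh$articular))
    pts <- pts[femoral_mesh$articular, , drop = FALSE]
  f <- insert$faces[insert$superior_faces, , drop = FALSE]
  v <- insert$vertices
  best <- Inf; best_p <- NULL
  for (i in seq_len(nrow(pts))) {
    for (j in seq_len(nrow(f))) {
      d <- oracle_point_tri_dist(pts[i, ], v[f[j, 1], ], v[f[j, 2], ],
                                 v[f[j, 3], ])
      if (d < best) {
        best <- d
        best_p <- pts[i, ]
      }
    }
  }
  list(dist = best, point = best_p)
}
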