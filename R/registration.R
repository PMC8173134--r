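# Rigid registration: point-to-point trimmed ICP between meshes/point sets
# and 6-DOF silhouette-based pose estimation from dual fluoroscopic views.

#' Registration result
#' @param pose recovered [rigid_pose()].
#' @param residual_rms root-mean-square residual (mm; on the detector for
#'   silhouette registration).
#' @param n_iterations iterations (ICP) or function evaluations (DFIS).
#' @param converged logical convergence flag.
#' @param residual_history per-iteration RMS (ICP only).
#' @return Object of class `registration_result`.
#' @export
registration_result <- function(pose, residual_rms, n_iterations, converged,
                                residual_history = NULL) {
  stopifnot(residual_rms >= 0)
  structure(list(pose = pose, residual_rms = residual_rms,
                 n_iterations = n_iterations, converged = converged,
                 residual_history = residual_history),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> rms %.4g mm, %d iterations, %s\n",
              x$residual_rms, x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# nearest target vertex for each source point, chunked brute force
nearest_vertex <- function(src, tgt) {
  n <- nrow(src)
  idx <- integer(n); d2 <- numeric(n)
  step <- max(1L, floor(2e6 / nrow(tgt)))
  t2 <- rowSums(tgt^2)
  for (s in seq(1L, n, by = step)) {
    e <- min(n, s + step - 1L)
    blk <- src[s:e, , drop = FALSE]
    # |x-y|^2 = |x|^2 - 2 x.y + |y|^2
    cr <- blk %*% t(tgt)
    dm <- outer(rowSums(blk^2), t2, "+") - 2 * cr
    j <- max.col(-dm, ties.method = "first")
    idx[s:e] <- j
    # recompute selected distances directly: the expansion above loses
    # precision to cancellation for near-coincident points
    d2[s:e] <- rowSums((blk - tgt[j, , drop = FALSE])^2)
  }
  list(index = idx, dist = sqrt(pmax(d2, 0)))
}

# closed-form rigid update (Kabsch, cross-covariance SVD)
kabsch <- function(src, tgt) {
  cs <- colMeans(src); ct <- colMeans(tgt)
  H <- crossprod(sweep(src, 2, cs), sweep(tgt, 2, ct))
  if (qr(H)$rank < 2)
    stop("icp_align: degenerate correspondence geometry")
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_pose(R, ct - as.numeric(R %*% cs))
}

#' Iterative closest point rigid alignment
#'
#' Point-to-point ICP of a source mesh (or point set) onto a target mesh:
#' per iteration, nearest-neighbour correspondences to the target vertices,
#' optional rejection of the worst `trim_fraction` by distance
#' (partial-overlap robustness), and a closed-form rigid update via the
#' cross-covariance SVD.  Stops when the RMS change falls below `tol`.
#'
#' @param source [surface_mesh()] or n x 3 point matrix (>= 100 points).
#' @param target [surface_mesh()].
#' @param max_iter iteration cap.
#' @param tol RMS change tolerance (mm).
#' @param trim_fraction fraction of worst correspondences rejected each
#'   iteration, in `[0, 0.5)`.
#' @param init optional initial [rigid_pose()].
#' @return A [registration_result()]; `pose` maps source to target.
#' @export
icp_align <- function(source, target, max_iter = 100, tol = 1e-10,
                      trim_fraction = 0, init = rigid_pose()) {
  src <- if (inherits(source, "surface_mesh")) source$vertices else
    as.matrix(source)
  tgt <- if (inherits(target, "surface_mesh")) target$vertices else
    as.matrix(target)
  if (nrow(src) < 100L) stop("icp_align: need at least 100 source points")
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    stop("icp_align: trim_fraction must be in [0, 0.5)")
  pose <- init
  rms_prev <- Inf
  hist <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    cur <- pose_apply(pose, src)
    nn <- nearest_vertex(cur, tgt)
    keep <- seq_len(nrow(cur))
    if (trim_fraction > 0) {
      k <- ceiling((1 - trim_fraction) * length(keep))
      keep <- order(nn$dist)[seq_len(k)]
    }
    rms <- sqrt(mean(nn$dist[keep]^2))
    hist <- c(hist, rms)
    if (is.finite(rms_prev) && abs(rms_prev - rms) < tol) {
      converged <- TRUE
      break
    }
    rms_prev <- rms
    upd <- kabsch(cur[keep, , drop = FALSE],
                  tgt[nn$index[keep], , drop = FALSE])
    pose <- pose_compose(upd, pose)
  }
  cur <- pose_apply(pose, src)
  nn <- nearest_vertex(cur, tgt)
  keep <- seq_len(nrow(cur))
  if (trim_fraction > 0)
    keep <- order(nn$dist)[seq_len(ceiling((1 - trim_fraction) *
                                             length(keep)))]
  registration_result(pose, sqrt(mean(nn$dist[keep]^2)), iter, converged,
                      residual_history = hist)
}

# squared distances from 2D points to the nearest of a set of 2D segments;
# segments-in-rows layout exploits column-wise vector recycling
point_segment_min_d2 <- function(pts, a, b) {
  d <- b - a
  len2 <- pmax(d[, 1]^2 + d[, 2]^2, 1e-300)
  wx <- outer(a[, 1], pts[, 1], "-"); wx <- -wx   # (p - a), k segs x m pts
  wy <- outer(a[, 2], pts[, 2], "-"); wy <- -wy
  # t = ((p - a) . d) / |d|^2, clamped to [0, 1]
  tt <- (wx * d[, 1] + wy * d[, 2]) / len2
  tt[tt < 0] <- 0; tt[tt > 1] <- 1
  fx <- tt * d[, 1] - wx
  fy <- tt * d[, 2] - wy
  dm <- fx * fx + fy * fy
  dm[cbind(max.col(-t(dm), ties.method = "first"), seq_len(ncol(dm)))]
}

#' Silhouette-based 6-DOF pose estimation (virtual dual-fluoroscopy)
#'
#' Recovers the pose of a component by minimizing, over both views, the
#' squared distances from each measured contour point to the nearest point
#' of the model's projected occluding contour at the candidate pose.  The
#' model silhouette is treated as a set of projected 2D segments so the
#' cost is exact along edges.  Optimization is derivative-free
#' (Nelder-Mead over the 6 Euler-translation parameters) with restarts at
#' the best point, since nearest-segment switching makes the cost
#' non-smooth.
#'
#' @param mesh watertight [surface_mesh()] of the component.
#' @param contours list of measured [contour_2d()] objects, one per view
#'   (at least 2 views; a single view leaves depth unconstrained and is
#'   refused).
#' @param cameras list of [camera_model()] objects matching `contours`.
#' @param initial_pose starting [rigid_pose()]; must be within the local
#'   basin (about 5 degrees / 10 mm).
#' @param optimizer_config list: `max_eval` total function-evaluation
#'   budget (default 2000 per view pair), `restarts` (default 4), `tol`
#'   cost-RMS change tolerance between restarts (mm, default 1e-4).
#' @return A [registration_result()] with the detector-plane RMS residual;
#'   non-convergence within budget is flagged, never silent.
#' @export
estimate_pose_dfis <- function(mesh, contours, cameras, initial_pose,
                               optimizer_config = list()) {
  if (length(contours) < 2L || length(cameras) < 2L)
    stop("estimate_pose_dfis: at least two views are required")
  if (length(contours) != length(cameras))
    stop("estimate_pose_dfis: contours/cameras length mismatch")
  cfg <- utils::modifyList(list(max_eval = 2000L, restarts = 4L,
                                tol = 1e-4), optimizer_config)
  topo <- mesh_edge_topology(mesh)
  npts <- sum(vapply(contours, function(ct) nrow(ct$points), 0L))
  cost <- function(par) {
    pose <- tryCatch(pose_from_params(par), error = function(e) NULL)
    if (is.null(pose)) return(1e12)
    tot <- 0
    for (k in seq_along(cameras)) {
      seg <- tryCatch(
        projected_silhouette_segments(mesh, pose, cameras[[k]], topo),
        error = function(e) NULL)
      if (is.null(seg)) return(1e12)
      tot <- tot + sum(point_segment_min_d2(contours[[k]]$points,
                                            seg$a, seg$b))
    }
    tot
  }
  par <- pose_params(initial_pose)
  best <- list(par = par, value = cost(par))
  evals <- 1L
  rms_prev <- Inf
  converged <- FALSE
  for (r in seq_len(cfg$restarts)) {
    left <- cfg$max_eval - evals
    if (left < 50L) break
    opt <- stats::optim(best$par, cost, method = "Nelder-Mead",
                        control = list(maxit = min(450L, left),
                                       reltol = 1e-14))
    evals <- evals + opt$counts[["function"]]
    if (opt$value < best$value) best <- list(par = opt$par,
                                             value = opt$value)
    rms <- sqrt(best$value / npts)
    # converged when the cost RMS is itself below tolerance or has
    # stopped improving between restarts
    if (rms < cfg$tol || abs(rms_prev - rms) < cfg$tol) {
      converged <- TRUE
      break
    }
    rms_prev <- rms
  }
  registration_result(pose_from_params(best$par),
                      sqrt(best$value / npts), evals, converged)
}
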