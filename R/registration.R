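# Rigid registration of the expanded pressure cloud (source) onto the
# mattress scan (target): deterministic coarse initialisation by centroid
# and in-plane principal axes, then point-to-point ICP refined by the
# Kabsch / SVD least-squares rigid fit.

#' Construct a rigid transform
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector in mm.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (length(translation) != 3)
    stop_vecforce("translation must have length 3", "validation_error")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop_vecforce("rotation must be orthonormal with det +1", "validation_error")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.2f, %.2f, %.2f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Rotation about z by an angle in radians
#' @param theta angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Rotation angle (degrees) of a rotation matrix
#' @param R 3x3 rotation matrix.
#' @return angle in degrees in \[0, 180\].
#' @export
rotation_angle_deg <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' Compose two rigid transforms (apply `a` after `b`)
#' @param a,b [rigid_transform()]s.
#' @return the composite transform a.b.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param t a [rigid_transform()].
#' @return the inverse transform.
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$rotation), -as.vector(t(t$rotation) %*% t$translation))
}

#' Apply a rigid transform to a surface cloud
#'
#' Points map as `p' = R p + t`; normals are rotated only.
#'
#' @param cloud a [surface_cloud()].
#' @param t a [rigid_transform()].
#' @param frame frame name for the result (default keeps the cloud's).
#' @return the transformed [surface_cloud()].
#' @export
apply_transform <- function(cloud, t, frame = cloud$frame) {
  pts <- cloud$points %*% t(t$rotation)
  pts <- sweep(pts, 2, t$translation, `+`)
  nrm <- if (!is.null(cloud$normals)) cloud$normals %*% t(t$rotation)
  surface_cloud(pts, nrm, frame = frame)
}

#' Serialise / deserialise a rigid transform as JSON
#'
#' @param t a [rigid_transform()].
#' @param path file path.
#' @return `path` (write) or a [rigid_transform()] (read).
#' @export
write_transform <- function(t, path) {
  jsonlite::write_json(list(rotation = t$rotation, translation = t$translation),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::fromJSON(path)
  R <- if (is.matrix(obj$rotation)) obj$rotation
  else matrix(obj$rotation, 3, 3, byrow = TRUE)
  rigid_transform(R, obj$translation)
}

nn_rmse <- function(src_pts, tgt_pts, sample_n = 2000L) {
  if (nrow(src_pts) > sample_n) {
    idx <- round(seq(1L, nrow(src_pts), length.out = sample_n))
    src_pts <- src_pts[idx, , drop = FALSE]
  }
  d <- RANN::nn2(tgt_pts, src_pts, k = 1L)$nn.dists
  sqrt(mean(d^2))
}

#' Coarse alignment by centroids and in-plane principal axes
#'
#' Deterministic surrogate for manual pre-alignment: translates the source
#' centroid onto the target centroid and rotates about z so that the
#' principal axes of the x-y spread coincide. The four in-plane sign/axis
#' assignments are all evaluated and the one with the smallest
#' nearest-neighbour RMSE wins. If `init` is supplied it is returned
#' unchanged.
#'
#' @param source,target [surface_cloud()]s.
#' @param init optional user-supplied [rigid_transform()] (pass-through).
#' @return a [rigid_transform()] mapping source into the target frame.
#' @export
coarse_align <- function(source, target, init = NULL) {
  if (!is.null(init)) return(init)
  if (!nrow(source$points) || !nrow(target$points))
    stop_vecforce("cannot align an empty cloud", "input_error")
  cs <- colMeans(source$points)
  ct <- colMeans(target$points)
  ang_of <- function(pts) {
    xy <- sweep(pts[, 1:2, drop = FALSE], 2, colMeans(pts[, 1:2, drop = FALSE]))
    e <- eigen(crossprod(xy) / nrow(xy), symmetric = TRUE)
    atan2(e$vectors[2, 1], e$vectors[1, 1])
  }
  if (nrow(source$points) < 3 || nrow(target$points) < 3) {
    return(rigid_transform(diag(3), ct - cs))
  }
  base <- ang_of(target$points) - ang_of(source$points)
  best <- NULL
  for (dth in c(0, pi / 2, pi, 3 * pi / 2)) {
    R <- rot_z(base + dth)
    t <- ct - as.vector(R %*% cs)
    moved <- sweep(source$points %*% t(R), 2, t, `+`)
    r <- nn_rmse(moved, target$points)
    if (is.null(best) || r < best$r) best <- list(R = R, t = t, r = r)
  }
  rigid_transform(best$R, best$t)
}

#' Point-to-point ICP refinement
#'
#' Classic iterative closest point: at each iteration, each source point is
#' matched to its nearest target point, pairs farther than `max_corr_dist`
#' are dropped, and the least-squares rigid transform of the surviving
#' pairs is found by SVD (Kabsch). Iteration stops when the inlier RMSE
#' changes by less than `tol` (relative) or `max_iter` is reached.
#'
#' @param source,target [surface_cloud()]s.
#' @param t0 initial [rigid_transform()] (e.g. from [coarse_align()]).
#' @param max_corr_dist correspondence cut-off in mm (default two cell
#'   pitches, 72.5 mm).
#' @param max_iter iteration cap.
#' @param tol relative RMSE change for convergence.
#' @return an object of class `registration_result`: `transform`, `rmse`
#'   (mm), `inlier_fraction`, `iterations`, `rmse_trace`.
#' @export
icp_refine <- function(source, target, t0 = rigid_transform(),
                       max_corr_dist = 2 * CELL_PITCH_MM,
                       max_iter = 200L, tol = 1e-6) {
  if (!nrow(source$points) || !nrow(target$points))
    stop_vecforce("cannot register an empty cloud", "input_error")
  if (max_corr_dist <= 0)
    stop_vecforce("max_corr_dist must be > 0", "parameter_error")
  src0 <- source$points
  R <- t0$rotation; tv <- t0$translation
  rmse_prev <- Inf
  trace <- numeric(0)
  iters <- 0L
  inlier_frac <- 0
  for (it in seq_len(max_iter)) {
    moved <- sweep(src0 %*% t(R), 2, tv, `+`)
    nn <- RANN::nn2(target$points, moved, k = 1L)
    ok <- nn$nn.dists[, 1] <= max_corr_dist
    if (!any(ok))
      stop_vecforce(sprintf(
        "no correspondences within %.3g mm (nearest pair %.3g mm): bad initial transform or cut-off",
        max_corr_dist, min(nn$nn.dists)), "convergence_error")
    p <- moved[ok, , drop = FALSE]
    q <- target$points[nn$nn.idx[ok, 1], , drop = FALSE]
    rmse <- sqrt(mean(nn$nn.dists[ok, 1]^2))
    trace <- c(trace, rmse)
    iters <- it
    inlier_frac <- mean(ok)
    if (is.finite(rmse_prev) &&
        abs(rmse_prev - rmse) <= tol * max(rmse_prev, .Machine$double.eps))
      break
    rmse_prev <- rmse
    # Kabsch on current correspondences, composed onto the running transform
    cp <- colMeans(p); cq <- colMeans(q)
    H <- crossprod(sweep(p, 2, cp), sweep(q, 2, cq))
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    Rd <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    td <- cq - as.vector(Rd %*% cp)
    R <- Rd %*% R
    tv <- as.vector(Rd %*% tv) + td
  }
  structure(list(transform = rigid_transform(R, tv),
                 rmse = trace[length(trace)],
                 inlier_fraction = inlier_frac,
                 iterations = iters,
                 rmse_trace = trace),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> rmse %.4g mm, %d iterations, %.0f%% inliers\n",
              x$rmse, x$iterations, 100 * x$inlier_fraction))
  invisible(x)
}

#' Register a pressure cloud to a mattress scan
#'
#' Convenience wrapper: [coarse_align()] then [icp_refine()].
#'
#' @inheritParams icp_refine
#' @param init optional initial transform forwarded to [coarse_align()].
#' @return a `registration_result`.
#' @export
register_clouds <- function(source, target, init = NULL,
                            max_corr_dist = 2 * CELL_PITCH_MM,
                            max_iter = 200L, tol = 1e-6) {
  t0 <- coarse_align(source, target, init)
  icp_refine(source, target, t0, max_corr_dist, max_iter, tol)
}
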