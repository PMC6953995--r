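#' Least-squares similarity alignment of two point sets
#'
#' Closed-form Procrustes (Kabsch/Umeyama) solution of
#' `min_{s,R,t} sum_i || s R x_i + t - y_i ||^2` with a proper rotation
#' (`det(R) = +1`), optionally without scale.
#'
#' @param source `n x 3` matrix of points to be moved.
#' @param target `n x 3` matrix of reference points (same `n >= 3`).
#' @param allow_scale estimate a scale factor (default `TRUE`).
#' @return list with `s` (scalar), `R` (3 x 3), `t` (length 3), `residual`
#'   (root-mean-square alignment error). Apply as `s * R %*% x + t`.
#' @export
procrustes_align <- function(source, target, allow_scale = TRUE) {
  source <- as.matrix(source); target <- as.matrix(target)
  n <- nrow(source)
  if (n != nrow(target)) stop("procrustes_align: point counts differ")
  if (n < 3L) stop("procrustes_align: at least 3 points required")
  mx <- colMeans(source); my <- colMeans(target)
  Xc <- sweep(source, 2L, mx); Yc <- sweep(target, 2L, my)
  sigma_x <- sum(Xc^2) / n
  if (sigma_x == 0) stop("procrustes_align: degenerate (coincident) source points")
  Sigma <- crossprod(Yc, Xc) / n
  sv <- svd(Sigma)
  if (sum(sv$d > max(sv$d) * 1e-10) < 2L)
    stop("procrustes_align: degenerate configuration (rank < 2)")
  S <- diag(3L)
  if (det(sv$u) * det(sv$v) < 0) S[3L, 3L] <- -1
  R <- sv$u %*% S %*% t(sv$v)
  s <- if (allow_scale) sum(diag(diag(sv$d) %*% S)) / sigma_x else 1
  t <- my - s * as.numeric(R %*% mx)
  fitted <- sweep(source %*% t(R) * s, 2L, t, "+")
  list(s = s, R = R, t = t,
       residual = sqrt(mean(rowSums((fitted - target)^2))))
}

# Inverse of a similarity transform.
invert_similarity <- function(trafo) {
  Rt <- t(trafo$R)
  list(s = 1 / trafo$s, R = Rt, t = -as.numeric(Rt %*% trafo$t) / trafo$s)
}

#' Generalized Procrustes alignment of corresponded meshes
#'
#' Iteratively aligns each configuration to the running mean until the mean
#' stabilizes, removing similarity (pose and, optionally, scale) effects and
#' leaving only shape. The mean is centered at the origin and renormalized
#' each iteration to a fixed reference centroid size: by default the average
#' centroid size of the inputs, which keeps model-frame coordinates in
#' millimetres; `scale_to = "unit"` gives the classical unit-size convention.
#'
#' @param meshes list of `triangle_mesh` objects in dense correspondence
#'   (shared topology), or a list of `n x 3` point matrices.
#' @param allow_scale align with per-shape scaling (default `TRUE`).
#' @param scale_to `"mean_size"` (default) or `"unit"` reference size for the
#'   mean shape.
#' @param tol relative mean-change convergence tolerance.
#' @param max_iter iteration cap.
#' @return list with `aligned` (list, same type as input), `mean` (mesh or
#'   matrix), `iterations`, `mean_change`.
#' @export
generalized_procrustes <- function(meshes, allow_scale = TRUE,
                                   scale_to = c("mean_size", "unit"),
                                   tol = 1e-7, max_iter = 100L) {
  scale_to <- match.arg(scale_to)
  if (!length(meshes)) stop("generalized_procrustes: empty collection")
  is_mesh <- inherits(meshes[[1L]], "triangle_mesh")
  configs <- if (is_mesh) lapply(meshes, `[[`, "points") else
    lapply(meshes, as.matrix)
  n <- nrow(configs[[1L]])
  if (any(vapply(configs, nrow, integer(1L)) != n))
    stop("generalized_procrustes: shapes are not in correspondence (vertex counts differ)")
  ref_size <- if (scale_to == "unit") 1 else
    mean(vapply(configs, centroid_size, numeric(1L)))
  normalize <- function(pts) {
    pts <- sweep(pts, 2L, colMeans(pts))
    pts * (ref_size / centroid_size(pts))
  }
  mean_pts <- normalize(configs[[1L]])
  aligned <- configs
  change <- Inf
  iter <- 0L
  while (iter < max_iter && change > tol) {
    iter <- iter + 1L
    aligned <- lapply(configs, function(pts) {
      tr <- procrustes_align(pts, mean_pts, allow_scale = allow_scale)
      apply_similarity(pts, tr)
    })
    new_mean <- normalize(Reduce(`+`, aligned) / length(aligned))
    change <- sqrt(sum((new_mean - mean_pts)^2)) / sqrt(sum(mean_pts^2))
    mean_pts <- new_mean
  }
  if (is_mesh) {
    tl <- meshes[[1L]]$trilist
    aligned <- Map(function(pts, m)
      triangle_mesh(pts, tl, colors = m$colors, validate = FALSE),
      aligned, meshes)
    mean_out <- triangle_mesh(mean_pts, tl, validate = FALSE)
  } else {
    mean_out <- mean_pts
  }
  list(aligned = aligned, mean = mean_out, iterations = iter,
       mean_change = change)
}
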