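# Cylindrical UV flattening and the thin-plate-spline correspondence
# baseline. These exist as a comparison method: the registration pipeline
# proper uses the non-rigid ICP route, which avoids the cylindrical
# projection's distortion of regions that map poorly to a cylinder.

#' Cylindrical UV embedding of a mesh
#'
#' Embeds each vertex on a cylinder around a (roughly vertical) axis:
#' `u` is the azimuth angle (radians, 0 facing world `+z`), `v` the height
#' along the axis (mm). Also rasterizes UV-space maps of world XYZ (and
#' color, when present) with a coverage mask, by barycentric interpolation
#' over the mesh triangles in UV space.
#'
#' @param mesh a `triangle_mesh`.
#' @param axis_point a point on the cylinder axis (default: mesh centroid).
#' @param axis_dir axis direction (default world `+y`).
#' @param resolution raster size `c(H, W)` (default 512 x 512).
#' @param u_range,v_range raster extents; default the data range padded 2%.
#' @return a `uv_embedding`: `uv` (`n x 2`), raster `xyz` (`H x W x 3`),
#'   `color` (or `NULL`), `mask`, `u_range`, `v_range`, and the source
#'   `mesh`.
#' @export
cylindrical_uv_embed <- function(mesh, axis_point = colMeans(mesh$points),
                                 axis_dir = c(0, 1, 0),
                                 resolution = c(512L, 512L),
                                 u_range = NULL, v_range = NULL) {
  d <- axis_dir / sqrt(sum(axis_dir^2))
  # reference direction for azimuth zero: world +z projected off the axis
  e1 <- c(0, 0, 1) - sum(c(0, 0, 1) * d) * d
  if (sqrt(sum(e1^2)) < 1e-9) e1 <- c(1, 0, 0) - sum(c(1, 0, 0) * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2L] * e1[3L] - d[3L] * e1[2L],
          d[3L] * e1[1L] - d[1L] * e1[3L],
          d[1L] * e1[2L] - d[2L] * e1[1L])
  rel <- sweep(mesh$points, 2L, axis_point)
  u <- atan2(rel %*% e2, rel %*% e1)[, 1L]
  v <- (rel %*% d)[, 1L]
  uv <- cbind(u = u, v = v)
  pad <- function(r) r + c(-1, 1) * 0.02 * max(diff(r), 1e-9)
  if (is.null(u_range)) u_range <- pad(range(u))
  if (is.null(v_range)) v_range <- pad(range(v))
  attrs <- list(xyz = mesh$points)
  if (!is.null(mesh$colors)) attrs$color <- mesh$colors
  maps <- rasterize_uv(uv, mesh$trilist, attrs, resolution, u_range, v_range)
  structure(list(uv = uv, xyz = maps$xyz, color = maps$color,
                 mask = maps$mask, resolution = as.integer(resolution),
                 u_range = u_range, v_range = v_range, mesh = mesh),
            class = "uv_embedding")
}

# Affine (non-perspective) rasterization of per-vertex attributes over the
# mesh triangles in UV space. Later triangles overwrite earlier ones where
# they overlap (a cylindrical face projection is essentially injective).
rasterize_uv <- function(uv, trilist, attrs, resolution, u_range, v_range) {
  H <- resolution[1L]; W <- resolution[2L]
  # pixel (r, c) center at uv coordinates:
  ucoord <- function(c) u_range[1L] + (c - 0.5) / W * diff(u_range)
  vcoord <- function(r) v_range[1L] + (r - 0.5) / H * diff(v_range)
  px <- (uv[, 1L] - u_range[1L]) / diff(u_range) * W + 0.5
  py <- (uv[, 2L] - v_range[1L]) / diff(v_range) * H + 0.5
  out <- lapply(attrs, function(a) array(NaN, c(H, W, ncol(a))))
  mask <- matrix(FALSE, H, W)
  for (ti in seq_len(nrow(trilist))) {
    vtx <- trilist[ti, ]
    x1 <- px[vtx[1L]]; y1 <- py[vtx[1L]]
    x2 <- px[vtx[2L]]; y2 <- py[vtx[2L]]
    x3 <- px[vtx[3L]]; y3 <- py[vtx[3L]]
    # skip triangles wrapping the azimuth seam
    if (max(x1, x2, x3) - min(x1, x2, x3) > W / 2) next
    cmin <- max(1L, ceiling(min(x1, x2, x3)))
    cmax <- min(W, floor(max(x1, x2, x3)))
    rmin <- max(1L, ceiling(min(y1, y2, y3)))
    rmax <- min(H, floor(max(y1, y2, y3)))
    if (cmin > cmax || rmin > rmax) next
    det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
    if (abs(det) < 1e-12) next
    cols <- cmin:cmax; rows <- rmin:rmax
    gx <- rep(cols, each = length(rows)) - x1
    gy <- rep(rows, times = length(cols)) - y1
    l2 <- (gx * (y3 - y1) - gy * (x3 - x1)) / det
    l3 <- (gy * (x2 - x1) - gx * (y2 - y1)) / det
    l1 <- 1 - l2 - l3
    inside <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    if (!any(inside)) next
    ridx <- rep(rows, times = length(cols))[inside]
    cidx <- rep(cols, each = length(rows))[inside]
    lin <- ridx + (cidx - 1L) * H
    mask[lin] <- TRUE
    for (nm in names(attrs)) {
      a <- attrs[[nm]]
      for (k in seq_len(ncol(a))) {
        off <- (k - 1L) * H * W
        out[[nm]][lin + off] <- l1[inside] * a[vtx[1L], k] +
          l2[inside] * a[vtx[2L], k] + l3[inside] * a[vtx[3L], k]
      }
    }
  }
  list(xyz = out$xyz, color = out$color, mask = mask)
}

# Continuous (x=col, y=row) raster coordinates of UV points in an embedding.
uv_to_raster <- function(embed, uv) {
  W <- embed$resolution[2L]; H <- embed$resolution[1L]
  cbind((uv[, 1L] - embed$u_range[1L]) / diff(embed$u_range) * W + 0.5,
        (uv[, 2L] - embed$v_range[1L]) / diff(embed$v_range) * H + 0.5)
}

#' Fit a 2D thin-plate spline through landmark correspondences
#'
#' Exact interpolating TPS: an affine part plus `r^2 log r` radial basis
#' terms centered on the source landmarks, solved in closed form. Maps 2D
#' source points to 2D targets; exact at the landmarks, affine maps are
#' reproduced with zero bending energy.
#'
#' @param src,dst `L x 2` matrices of corresponding 2D points, `L >= 4`,
#'   sources not collinear.
#' @return a `tps_warp` (use [tps_apply()]).
#' @export
tps_fit <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  L <- nrow(src)
  if (L < 4L) stop("tps_fit: at least 4 landmark pairs required")
  P <- cbind(1, src)
  if (qr(P)$rank < 3L)
    stop("tps_fit: degenerate (collinear) landmark configuration")
  if (anyDuplicated(round(src, 10L)))
    stop("tps_fit: duplicate source landmark positions")
  K <- tps_kernel_matrix(src, src)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3L, 3L)))
  b <- rbind(dst, matrix(0, 3L, 2L))
  sol <- solve(A, b)
  structure(list(src = src, w = sol[seq_len(L), , drop = FALSE],
                 a = sol[L + 1:3, , drop = FALSE]),
            class = "tps_warp")
}

tps_kernel_matrix <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
  d2 <- pmax(d2, 0)
  out <- matrix(0, nrow(x), nrow(centers))
  nz <- d2 > 0
  out[nz] <- d2[nz] * log(d2[nz]) / 2  # r^2 log r == d2 log(sqrt(d2))
  out
}

#' @rdname tps_fit
#' @param warp a fitted `tps_warp`.
#' @param x `q x 2` points to map.
#' @export
tps_apply <- function(warp, x) {
  x <- as.matrix(x)
  cbind(1, x) %*% warp$a + tps_kernel_matrix(x, warp$src) %*% warp$w
}

#' UV-space TPS dense correspondence (baseline method)
#'
#' The classical UV-route to dense correspondence: both meshes are flattened
#' to cylindrical UV space, a thin-plate spline fitted through the sparse
#' landmark correspondences maps every template vertex's UV site into the
#' target UV frame, and the target's XYZ UV map is sampled there
#' (bilinearly) to rebuild a mesh on the template topology.
#'
#' @param template_uv,target_uv `uv_embedding`s of template and target.
#' @param template_landmarks_uv,target_landmarks_uv `L x 2` UV coordinates of
#'   corresponding landmarks (`L >= 4`, non-collinear).
#' @return a `triangle_mesh` on the template topology (colors sampled from
#'   the target color map when available).
#' @export
uv_tps_register <- function(template_uv, target_uv,
                            template_landmarks_uv, target_landmarks_uv) {
  warp <- tps_fit(template_landmarks_uv, target_landmarks_uv)
  mapped <- tps_apply(warp, template_uv$uv)
  rc <- uv_to_raster(target_uv, mapped)
  n <- nrow(mapped)
  pts <- matrix(NaN, n, 3L)
  cols <- if (!is.null(target_uv$color)) matrix(NaN, n, 3L)
  for (i in seq_len(n)) {
    s <- bilinear_covered(target_uv$xyz, target_uv$mask, rc[i, 1L], rc[i, 2L])
    if (s$weight > 0) {
      pts[i, ] <- s$value
      if (!is.null(cols)) {
        sc <- bilinear_covered(target_uv$color, target_uv$mask,
                               rc[i, 1L], rc[i, 2L])
        cols[i, ] <- pmin(pmax(sc$value, 0), 1)
      }
    }
  }
  # vertices mapping outside the target's covered UV area: fall back to the
  # nearest covered sample so the output is a complete mesh
  bad <- !is.finite(pts[, 1L])
  if (any(bad)) {
    cov <- which(target_uv$mask, arr.ind = TRUE)
    for (i in which(bad)) {
      d2 <- (cov[, 2L] - rc[i, 1L])^2 + (cov[, 1L] - rc[i, 2L])^2
      j <- which.min(d2)
      pts[i, ] <- target_uv$xyz[cov[j, 1L], cov[j, 2L], ]
      if (!is.null(cols))
        cols[i, ] <- pmin(pmax(target_uv$color[cov[j, 1L], cov[j, 2L], ], 0), 1)
    }
  }
  triangle_mesh(pts, template_uv$mesh$trilist, colors = cols, validate = FALSE)
}
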