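#' Perspective virtual camera
#'
#' A pinhole camera: a rigid world-to-camera transform plus a perspective
#' projection with focal length and principal point in pixel units. Pixel
#' `(row, col)` has its center at continuous image coordinates `(x, y) =
#' (col, row)`; a point at camera coordinates `(xc, yc, zc)` (with `zc > 0`
#' in front of the camera) projects to `x = focal * xc / zc + cx`,
#' `y = focal * yc / zc + cy`.
#'
#' @param R 3x3 rotation, world to camera.
#' @param eye camera center in world coordinates (mm).
#' @param focal focal length in pixels.
#' @param image_size `c(height, width)` in pixels.
#' @param principal principal point `c(cx, cy)`; defaults to the image center.
#' @return a `virtual_camera`.
#' @export
virtual_camera <- function(R, eye, focal, image_size,
                           principal = c((image_size[2L] + 1) / 2,
                                         (image_size[1L] + 1) / 2)) {
  R <- as.matrix(R)
  if (abs(det(R)) < 1e-8) stop("virtual_camera: projection matrix rank-deficient")
  if (any(image_size < 1)) stop("virtual_camera: image size must be positive")
  if (focal <= 0) stop("virtual_camera: focal length must be positive")
  structure(list(R = R, eye = as.numeric(eye), focal = focal,
                 image_size = as.integer(image_size),
                 principal = as.numeric(principal)),
            class = "virtual_camera")
}

#' @rdname virtual_camera
#' @param target world point the camera looks at.
#' @param up approximate world up direction.
#' @export
look_at_camera <- function(eye, target, focal, image_size, up = c(0, 1, 0)) {
  z <- target - eye
  z <- z / sqrt(sum(z^2))
  x <- c(up[2L] * z[3L] - up[3L] * z[2L],
         up[3L] * z[1L] - up[1L] * z[3L],
         up[1L] * z[2L] - up[2L] * z[1L])
  nx <- sqrt(sum(x^2))
  if (nx < 1e-12) stop("look_at_camera: view direction parallel to up")
  x <- x / nx
  y <- c(z[2L] * x[3L] - z[3L] * x[2L],
         z[3L] * x[1L] - z[1L] * x[3L],
         z[1L] * x[2L] - z[2L] * x[1L])
  virtual_camera(rbind(x, y, z), eye, focal, image_size)
}

#' Project world points through a camera
#'
#' @param camera a `virtual_camera`.
#' @param points `n x 3` world points.
#' @return `n x 3` matrix: image `x`, image `y`, camera depth `z` (mm).
#' @export
project_points <- function(camera, points) {
  pc <- sweep(as.matrix(points), 2L, camera$eye) %*% t(camera$R)
  z <- pc[, 3L]
  cbind(x = camera$focal * pc[, 1L] / z + camera$principal[1L],
        y = camera$focal * pc[, 2L] / z + camera$principal[2L],
        z = z)
}

#' Default multi-view camera rig around a mesh
#'
#' A yaw arc of perspective cameras at a fixed distance scaled to the mesh's
#' bounding sphere, all looking at the mesh centroid: a frontal view plus
#' symmetric side views covers the self-occlusions of a face-like surface.
#'
#' @param mesh a `triangle_mesh` (assumed to face the world `+z` axis with
#'   `+y` up).
#' @param yaw_deg yaw angles of the rig (degrees; 0 = frontal).
#' @param image_size rendered image size `c(H, W)` (default 512 x 512).
#' @param distance_factor camera distance as a multiple of the bounding
#'   sphere radius.
#' @param fill_factor fraction of the image the bounding sphere should span.
#' @return list of `virtual_camera`s, in the order of `yaw_deg`.
#' @export
default_camera_rig <- function(mesh, yaw_deg = c(0, -30, 30, -60, 60),
                               image_size = c(512L, 512L),
                               distance_factor = 3, fill_factor = 0.8) {
  center <- colMeans(mesh$points)
  radius <- sqrt(max(rowSums(sweep(mesh$points, 2L, center)^2)))
  dist <- distance_factor * radius
  focal <- fill_factor * min(image_size) * dist / (2 * radius)
  lapply(yaw_deg, function(th) {
    a <- th * pi / 180
    eye <- center + dist * c(sin(a), 0, cos(a))
    look_at_camera(eye, center, focal, image_size)
  })
}

#' Render z-buffered views of a mesh
#'
#' Rasterizes the mesh through each camera with perspective-correct
#' barycentric interpolation, producing per view an RGB texture image, an XYZ
#' shape image holding the world coordinates of the surface point seen by
#' each pixel, a depth buffer and a coverage mask. Rendering is unlit
#' (vertex colors reproduced directly — the shape image, the quantity the
#' landmarking relies on, is light-independent) with optional back-face
#' culling. A camera seeing no surface yields an empty (all-uncovered) view,
#' not an error.
#'
#' @param mesh a `triangle_mesh`; a uniform mid-gray is used when it has no
#'   colors.
#' @param cameras list of `virtual_camera`s.
#' @param background texture fill value for uncovered pixels.
#' @param cull_backfaces skip triangles facing away from the camera.
#' @return list of `rendered_view` objects: `texture` (`H x W x 3`), `shape`
#'   (`H x W x 3`, `NaN` outside coverage), `depth` (`H x W`), `mask`
#'   (`H x W` logical), `camera`, `empty` flag.
#' @export
render_views <- function(mesh, cameras, background = 0.2,
                         cull_backfaces = TRUE) {
  validate_mesh(mesh)
  colors <- mesh$colors
  if (is.null(colors))
    colors <- matrix(0.5, nrow(mesh$points), 3L)
  lapply(cameras, function(cam)
    render_one_view(mesh, colors, cam, background, cull_backfaces))
}

render_one_view <- function(mesh, colors, cam, background, cull_backfaces) {
  H <- cam$image_size[1L]; W <- cam$image_size[2L]
  pc <- sweep(mesh$points, 2L, cam$eye) %*% t(cam$R)  # camera frame
  z <- pc[, 3L]
  px <- cam$focal * pc[, 1L] / z + cam$principal[1L]
  py <- cam$focal * pc[, 2L] / z + cam$principal[2L]

  zbuf <- matrix(Inf, H, W)
  shape <- array(NaN, c(H, W, 3L))
  texture <- array(background, c(H, W, 3L))
  tl <- mesh$trilist
  near <- 1e-6

  for (ti in seq_len(nrow(tl))) {
    v <- tl[ti, ]
    if (any(z[v] <= near)) next  # behind/at the camera plane
    if (cull_backfaces) {
      e1 <- pc[v[2L], ] - pc[v[1L], ]
      e2 <- pc[v[3L], ] - pc[v[1L], ]
      nrm <- c(e1[2L] * e2[3L] - e1[3L] * e2[2L],
               e1[3L] * e2[1L] - e1[1L] * e2[3L],
               e1[1L] * e2[2L] - e1[2L] * e2[1L])
      if (sum(nrm * pc[v[1L], ]) >= 0) next  # normal points away from camera
    }
    x1 <- px[v[1L]]; y1 <- py[v[1L]]
    x2 <- px[v[2L]]; y2 <- py[v[2L]]
    x3 <- px[v[3L]]; y3 <- py[v[3L]]
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
    iz <- l1 / z[v[1L]] + l2 / z[v[2L]] + l3 / z[v[3L]]  # 1/z interpolates linearly
    depth <- 1 / iz
    ridx <- rep(rows, times = length(cols))[inside]
    cidx <- rep(cols, each = length(rows))[inside]
    lin <- ridx + (cidx - 1L) * H
    better <- depth[inside] < zbuf[lin]
    if (!any(better)) next
    lin <- lin[better]
    sel <- which(inside)[better]
    # perspective-correct weights
    w1 <- (l1[sel] / z[v[1L]]) / iz[sel]
    w2 <- (l2[sel] / z[v[2L]]) / iz[sel]
    w3 <- (l3[sel] / z[v[3L]]) / iz[sel]
    zbuf[lin] <- depth[sel]
    for (k in 1:3) {
      off <- (k - 1L) * H * W
      shape[lin + off] <- w1 * mesh$points[v[1L], k] +
        w2 * mesh$points[v[2L], k] + w3 * mesh$points[v[3L], k]
      texture[lin + off] <- w1 * colors[v[1L], k] +
        w2 * colors[v[2L], k] + w3 * colors[v[3L], k]
    }
  }
  mask <- is.finite(zbuf)
  structure(list(texture = texture, shape = shape, depth = zbuf,
                 mask = mask, camera = cam, empty = !any(mask)),
            class = "rendered_view")
}

#' @export
print.rendered_view <- function(x, ...) {
  cat(sprintf("rendered_view: %d x %d, %.1f%% covered%s\n",
              nrow(x$mask), ncol(x$mask), 100 * mean(x$mask),
              if (x$empty) " (empty)" else ""))
  invisible(x)
}

# Bilinear sample of an H x W (x C) image at continuous (x, y), restricted to
# covered pixels; weights over uncovered neighbours are renormalized away.
# Returns list(value, weight_total).
bilinear_covered <- function(img, mask, x, y) {
  H <- nrow(mask); W <- ncol(mask)
  c0 <- floor(x); r0 <- floor(y)
  fx <- x - c0; fy <- y - r0
  nb <- cbind(c(r0, r0, r0 + 1, r0 + 1), c(c0, c0 + 1, c0, c0 + 1))
  wt <- c((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  ok <- nb[, 1L] >= 1 & nb[, 1L] <= H & nb[, 2L] >= 1 & nb[, 2L] <= W
  ok[ok] <- mask[nb[ok, , drop = FALSE]]
  ok <- ok & wt > 0
  if (!any(ok)) return(list(value = rep(NaN, dim(img)[3L]), weight = 0))
  wt <- wt[ok] / sum(wt[ok])
  nb <- nb[ok, , drop = FALSE]
  val <- vapply(seq_len(dim(img)[3L]), function(k)
    sum(wt * img[cbind(nb, k)]), numeric(1L))
  list(value = val, weight = sum(ok) / 4)
}

#' Back-project 2D detections onto the rendered surface
#'
#' Looks up the world XYZ of each sub-pixel detection in the view's shape
#' image by bilinear interpolation over covered pixels. Detections whose four
#' neighbouring pixels are all uncovered (background) become masked
#' landmarks rather than errors.
#'
#' @param view a `rendered_view`.
#' @param pixels `L x 2` matrix of image `(x, y)` detections.
#' @param confidence per-detection confidence in `[0, 1]`.
#' @param labels landmark names.
#' @return a [landmark_set()] with confidences.
#' @export
backproject_landmarks <- function(view, pixels, confidence = NULL,
                                  labels = NULL) {
  pixels <- as.matrix(pixels)
  L <- nrow(pixels)
  if (is.null(labels)) labels <- paste0("lm_", seq_len(L))
  if (is.null(confidence)) confidence <- rep(1, L)
  H <- nrow(view$mask); W <- ncol(view$mask)
  pts <- matrix(NaN, L, 3L)
  valid <- logical(L)
  for (i in seq_len(L)) {
    x <- pixels[i, 1L]; y <- pixels[i, 2L]
    if (!is.finite(x) || !is.finite(y) || x < 0.5 || x > W + 0.5 ||
        y < 0.5 || y > H + 0.5) next
    s <- bilinear_covered(view$shape, view$mask, x, y)
    if (s$weight > 0) {
      pts[i, ] <- s$value
      valid[i] <- TRUE
    }
  }
  landmark_set(labels, pts, valid = valid, confidence = confidence)
}

#' Composite per-view landmark sets into a master annotation
#'
#' For each label, keeps the valid candidate with the highest detector
#' confidence (zero-confidence detections never qualify); ties resolve to the
#' earliest view in the configured camera order. Labels valid in no view are
#' masked in the output.
#'
#' @param per_view non-empty list of [landmark_set()]s sharing one label
#'   vocabulary.
#' @return a composited [landmark_set()].
#' @export
composite_landmarks <- function(per_view) {
  if (!length(per_view)) stop("composite_landmarks: empty view list")
  labels <- per_view[[1L]]$labels
  for (s in per_view)
    if (!identical(s$labels, labels))
      stop("composite_landmarks: views disagree on the label vocabulary")
  L <- length(labels)
  pts <- matrix(NaN, L, 3L)
  valid <- logical(L)
  conf <- numeric(L)
  for (i in seq_len(L)) {
    best <- 0
    for (v in seq_along(per_view)) {
      s <- per_view[[v]]
      ci <- if (is.null(s$confidence)) 1 else s$confidence[i]
      if (s$valid[i] && ci > 0 && ci > best) {  # strict: ties keep earlier view
        best <- ci
        pts[i, ] <- s$points[i, ]
        valid[i] <- TRUE
        conf[i] <- ci
      }
    }
  }
  landmark_set(labels, pts, valid = valid, confidence = conf)
}

#' Fully automatic 3D landmarking of a raw mesh
#'
#' Renders the mesh from each camera, runs the 2D landmark detector on every
#' view, back-projects the detections to the surface through the per-pixel
#' shape images, and composites the per-view results into a master landmark
#' set. A detector that errors on one view only skips that view (with a
#' warning); it is an error for every view to fail.
#'
#' @param mesh a `triangle_mesh`.
#' @param cameras list of `virtual_camera`s (e.g. [default_camera_rig()]).
#' @param detector a 2D landmark detector: a function taking a
#'   `rendered_view` and returning `list(points = L x 2 pixel coordinates,
#'   confidence = numeric L in [0,1], labels = character L)`. Detectors that
#'   only use 2D appearance simply read `view$texture`.
#' @param labels landmark names, used when the detector does not supply them.
#' @return a composited [landmark_set()].
#' @export
auto_landmark <- function(mesh, cameras, detector, labels = NULL) {
  views <- render_views(mesh, cameras)
  per_view <- list()
  for (v in seq_along(views)) {
    det <- tryCatch(detector(views[[v]]), error = function(e) {
      warning("detector failed on view ", v, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(det)) next
    per_view[[length(per_view) + 1L]] <-
      backproject_landmarks(views[[v]], det$points, det$confidence,
                            labels = if (!is.null(det$labels)) det$labels else labels)
  }
  if (!length(per_view))
    stop("auto_landmark: detector failed on every view")
  composite_landmarks(per_view)
}

#' Resolve a 2D detector plug-in from a name
#'
#' Detector plug-ins are referenced in configuration files by a dotted path
#' `"package::function"` (or a bare function name on the search path); the
#' named function must be a factory returning a detector, or a detector
#' itself.
#'
#' @param spec a function (returned unchanged) or a character name.
#' @export
resolve_detector <- function(spec) {
  if (is.function(spec)) return(spec)
  if (!is.character(spec)) stop("resolve_detector: need a function or name")
  if (grepl("::", spec, fixed = TRUE)) {
    parts <- strsplit(spec, "::", fixed = TRUE)[[1L]]
    getExportedValue(parts[1L], parts[2L])
  } else {
    get(spec, mode = "function")
  }
}

#' Export a rendered view for debugging
#'
#' Writes the texture image as PNG and the XYZ shape image as a 3-channel
#' 32-bit float TIFF (requires the `png` and `tiff` packages).
#'
#' @param view a `rendered_view`.
#' @param prefix output path prefix (writes `<prefix>_texture.png`,
#'   `<prefix>_shape.tif`).
#' @export
export_view <- function(view, prefix) {
  if (requireNamespace("png", quietly = TRUE)) {
    png::writePNG(view$texture, paste0(prefix, "_texture.png"))
  } else warning("png package unavailable; texture not written")
  if (requireNamespace("tiff", quietly = TRUE)) {
    shp <- view$shape
    shp[!is.finite(shp)] <- 0
    rng <- range(shp)
    norm <- if (diff(rng) > 0) (shp - rng[1L]) / diff(rng) else shp * 0
    tiff::writeTIFF(norm, paste0(prefix, "_shape.tif"), bits.per.sample = 32L)
  } else warning("tiff package unavailable; shape image not written")
  invisible(prefix)
}
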