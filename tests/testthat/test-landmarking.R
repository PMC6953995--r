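# a single triangle facing the camera, with a per-pixel ray-triangle oracle

single_triangle_view <- function() {
  tri <- triangle_mesh(rbind(c(-20, -20, 0), c(20, -20, 0), c(0, 25, 0)),
                       matrix(c(1L, 2L, 3L), 1L),
                       colors = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  cam <- look_at_camera(eye = c(0, 0, 200), target = c(0, 0, 0),
                        focal = 300, image_size = c(64L, 64L))
  list(mesh = tri, cam = cam,
       view = render_views(tri, list(cam))[[1L]])
}

test_that("rasterized shape image matches the ray-triangle intersection oracle", {
  s <- single_triangle_view()
  v <- s$view
  expect_false(v$empty)
  covered <- which(v$mask, arr.ind = TRUE)
  expect_gt(nrow(covered), 100L)
  set.seed(2)
  pick <- covered[sample(nrow(covered), 25L), , drop = FALSE]
  R <- s$cam$R; eye <- s$cam$eye; f <- s$cam$focal; pp <- s$cam$principal
  a <- s$mesh$points[1L, ]; b <- s$mesh$points[2L, ]; c3 <- s$mesh$points[3L, ]
  for (i in seq_len(nrow(pick))) {
    r <- pick[i, 1L]; cc <- pick[i, 2L]
    # oracle: cast the pixel's ray and intersect with the triangle plane z=0
    dir_cam <- c((cc - pp[1L]) / f, (r - pp[2L]) / f, 1)
    dir_world <- as.numeric(t(R) %*% dir_cam)
    t_hit <- -eye[3L] / dir_world[3L]
    hit <- eye + t_hit * dir_world
    expect_equal(as.numeric(v$shape[r, cc, ]), hit, tolerance = 1e-6)
    # barycentric-combined vertex color at the hit point
    M <- cbind(a - c3, b - c3)
    l12 <- qr.solve(M[1:2, ], (hit - c3)[1:2])
    w <- c(l12, 1 - sum(l12))
    oracle_col <- as.numeric(w %*% s$mesh$colors)
    expect_equal(as.numeric(v$texture[r, cc, ]), oracle_col, tolerance = 1e-6)
  }
})

test_that("the z-buffer keeps the nearer of two overlapping triangles", {
  mesh <- triangle_mesh(
    rbind(c(-10, -10, 0), c(10, -10, 0), c(0, 12, 0),      # far
          c(-10, -10, 30), c(10, -10, 30), c(0, 12, 30)),  # near
    rbind(c(1L, 2L, 3L), c(4L, 5L, 6L)))
  cam <- look_at_camera(c(0, 0, 200), c(0, 0, 0), focal = 300,
                        image_size = c(64L, 64L))
  v <- render_views(mesh, list(cam), cull_backfaces = FALSE)[[1L]]
  z_near <- 170  # camera at z=200 looking at plane z=30
  covered_z <- v$shape[, , 3L][v$mask]
  expect_true(all(abs(covered_z - 30) < 1e-6))
  expect_true(all(abs(v$depth[v$mask] - z_near) < 2))
})

test_that("a camera looking away yields an empty, non-fatal view", {
  mesh <- tiny_template(0L)$mesh
  cam <- look_at_camera(c(0, 0, 500), c(0, 0, 1000), focal = 300,
                        image_size = c(32L, 32L))
  v <- render_views(mesh, list(cam))[[1L]]
  expect_true(v$empty)
  expect_false(any(v$mask))
  expect_true(all(!is.finite(v$shape[, , 1L])))
})

test_that("rendering is deterministic and shape is finite exactly on coverage", {
  mesh <- tiny_template(0L)$mesh
  cams <- default_camera_rig(mesh, image_size = c(96L, 96L))
  v1 <- render_views(mesh, cams)
  v2 <- render_views(mesh, cams)
  for (k in seq_along(cams)) {
    expect_identical(v1[[k]]$shape, v2[[k]]$shape)
    expect_identical(v1[[k]]$mask, v2[[k]]$mask)
    fin <- is.finite(v1[[k]]$shape[, , 1L])
    expect_identical(fin, v1[[k]]$mask)
  }
})

test_that("back-projection interpolates covered pixels and masks background", {
  s <- single_triangle_view()
  v <- s$view
  covered <- which(v$mask, arr.ind = TRUE)
  # pick an integer pixel whose 4 bilinear neighbours are covered
  inner <- covered[covered[, 1L] %in% 20:40 & covered[, 2L] %in% 20:40, ]
  r <- inner[1L, 1L]; cc <- inner[1L, 2L]
  res <- backproject_landmarks(v, rbind(c(cc, r)), confidence = 1,
                               labels = "node")
  expect_true(res$valid[1L])
  expect_equal(res$points[1L, ], v$shape[r, cc, ], tolerance = 1e-12)
  # center among 4 covered pixels -> average of the 4 values
  res2 <- backproject_landmarks(v, rbind(c(cc + 0.5, r + 0.5)), labels = "mid")
  nb <- rbind(v$shape[r, cc, ], v$shape[r, cc + 1L, ],
              v$shape[r + 1L, cc, ], v$shape[r + 1L, cc + 1L, ])
  expect_equal(res2$points[1L, ], colMeans(nb), tolerance = 1e-12)
  # background pixel -> masked landmark, not an error
  res3 <- backproject_landmarks(v, rbind(c(2, 2)), labels = "bg")
  expect_false(res3$valid[1L])
})

test_that("compositing keeps the highest-confidence valid candidate", {
  mk <- function(p, valid, conf)
    landmark_set(c("a", "b"), rbind(p, c(9, 9, 9)),
                 valid = c(valid, TRUE), confidence = c(conf, 0.5))
  va <- mk(c(1, 0, 0), TRUE, 0.9)
  vb <- mk(c(2, 0, 0), TRUE, 0.4)
  out <- composite_landmarks(list(va, vb))
  expect_equal(out$points[1L, ], c(1, 0, 0))
  # tie -> earliest view
  vc <- mk(c(3, 0, 0), TRUE, 0.9)
  out2 <- composite_landmarks(list(va, vc))
  expect_equal(out2$points[1L, ], c(1, 0, 0))
  # invalid everywhere -> masked
  out3 <- composite_landmarks(list(mk(c(1, 0, 0), FALSE, 0.9),
                                   mk(c(2, 0, 0), FALSE, 0.9)))
  expect_false(out3$valid[1L])
  expect_error(composite_landmarks(list()), "empty")
})

test_that("auto-landmarking with the oracle detector recovers ground truth", {
  tmpl <- tiny_template(1L)
  mesh <- tmpl$mesh
  cams <- default_camera_rig(mesh, image_size = c(256L, 256L))
  lms <- auto_landmark(mesh, cams, oracle_detector(tmpl$landmarks))
  expect_true(all(lms$valid))
  err <- sqrt(rowSums((lms$points - tmpl$landmarks$points)^2))
  # one-pixel surface footprint at this resolution and rig geometry
  center <- colMeans(mesh$points)
  radius <- sqrt(max(rowSums(sweep(mesh$points, 2L, center)^2)))
  footprint <- 2 * radius / (0.8 * 256)
  expect_lt(max(err), footprint)
  # every valid composited landmark lies on the surface
  d <- closest_point_on_surface(lms$points, mesh)$distance
  expect_lt(max(d), footprint)
})

test_that("zero-confidence detections leave all landmarks masked", {
  tmpl <- tiny_template(0L)
  cams <- default_camera_rig(tmpl$mesh, image_size = c(64L, 64L))
  det0 <- function(view) {
    d <- oracle_detector(tmpl$landmarks)(view)
    d$confidence[] <- 0
    d
  }
  out <- auto_landmark(tmpl$mesh, cams, det0)
  expect_false(any(out$valid))
})

test_that("a detector failing on one view is skipped; all views failing errors", {
  tmpl <- tiny_template(0L)
  cams <- default_camera_rig(tmpl$mesh, image_size = c(64L, 64L))
  calls <- 0L
  flaky <- function(view) {
    calls <<- calls + 1L
    if (calls == 1L) stop("detector crash")
    oracle_detector(tmpl$landmarks)(view)
  }
  expect_warning(out <- auto_landmark(tmpl$mesh, cams, flaky),
                 "failed on view 1")
  expect_true(any(out$valid))
  dead <- function(view) stop("nope")
  expect_error(
    suppressWarnings(auto_landmark(tmpl$mesh, cams, dead)), "every view")
})

test_that("occluded landmarks fall back to other views in the rig", {
  tmpl <- tiny_template(1L)
  mesh <- tmpl$mesh
  # profile view at +80 degrees: the left-side landmarks are self-occluded
  cams <- default_camera_rig(mesh, yaw_deg = c(80, 0), image_size = c(128L, 128L))
  det <- oracle_detector(tmpl$landmarks)
  views <- render_views(mesh, cams)
  d_profile <- det(views[[1L]])
  d_frontal <- det(views[[2L]])
  expect_gt(sum(d_profile$confidence == 0), 0L)  # someone is occluded
  expect_true(all(d_frontal$confidence == 1))
  out <- auto_landmark(mesh, cams, det)
  expect_true(all(out$valid))
  # landmarks occluded in the profile must have come from the frontal view,
  # with frontal-view accuracy
  fell_back <- d_profile$confidence == 0
  err <- sqrt(rowSums((out$points - tmpl$landmarks$points)^2))
  center <- colMeans(mesh$points)
  radius <- sqrt(max(rowSums(sweep(mesh$points, 2L, center)^2)))
  expect_lt(max(err[fell_back]), 2 * radius / (0.8 * 128))
})
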