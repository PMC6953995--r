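test_that("configuration invariants are enforced", {
  expect_error(nicp_config(stiffness_schedule = c(1, 2, 3),
                           landmark_schedule = c(1, 1, 1)), "decreasing")
  expect_error(nicp_config(stiffness_schedule = c(3, 2),
                           landmark_schedule = c(1, 1, 1)), "same length")
  expect_error(nicp_config(gamma = -1))
  cfg <- nicp_config()
  expect_length(cfg$stiffness_schedule, 8L)
  expect_true(all(diff(cfg$stiffness_schedule) < 0))
})

test_that("energy vanishes for identity transforms on a self-target", {
  tmpl <- tiny_template(0L)
  stack <- uniform_affine_stack(nrow(tmpl$mesh$points))
  e <- nicp_energy(stack, tmpl$mesh, tmpl$mesh, tmpl$landmarks,
                   tmpl$landmarks, nicp_config(), alpha = 3, beta = 2)
  expect_lt(e$E_d, 1e-16)
  expect_equal(e$E_s, 0)
  expect_lt(e$E_l, 1e-16)
})

test_that("a shared affine transform has zero stiffness energy", {
  tmpl <- tiny_template(0L)
  set.seed(1)
  A <- matrix(rnorm(12), 3L, 4L)
  n <- nrow(tmpl$mesh$points)
  stack <- affine_stack(do.call(rbind, replicate(n, t(A), simplify = FALSE)))
  e <- nicp_energy(stack, tmpl$mesh, tmpl$mesh, tmpl$landmarks,
                   tmpl$landmarks, nicp_config(), alpha = 1, beta = 0)
  expect_equal(e$E_s, 0, tolerance = 1e-18)
})

test_that("energy terms match the naive summation oracle on a small instance", {
  set.seed(6)
  # tiny template: 6 vertices, 4 triangles, connected
  tm <- triangle_mesh(matrix(rnorm(18, sd = 5), 6L, 3L),
                      rbind(c(1L, 2L, 3L), c(2L, 3L, 4L), c(3L, 4L, 5L),
                            c(4L, 5L, 6L)))
  target <- triangle_mesh(matrix(rnorm(18, sd = 5), 6L, 3L), tm$trilist)
  tlms <- landmark_set("lm1", tm$points[2L, , drop = FALSE],
                       template_indices = 2L)
  slms <- landmark_set("lm1", matrix(c(1, 2, 3), 1L))
  stack <- affine_stack(matrix(rnorm(24 * 3, sd = 0.5), 24L, 3L))
  cfg <- nicp_config(gamma = 1.7)
  got <- nicp_energy(stack, tm, target, tlms, slms, cfg,
                     alpha = 2.3, beta = 0.9)
  oracle <- oracle_nicp_energy(stack, tm, target, tlms, slms,
                               gamma = 1.7, alpha = 2.3, beta = 0.9,
                               steps = 400L)
  expect_equal(got$E_s, oracle$E_s, tolerance = 1e-10)
  expect_equal(got$E_l, oracle$E_l, tolerance = 1e-10)
  # data term oracle is a grid search: agreement to the grid resolution
  expect_equal(got$E_d, oracle$E_d, tolerance = 1e-2)
  expect_equal(got$E, oracle$E, tolerance = 1e-2)
})

test_that("registering the template to itself is exact", {
  tmpl <- tiny_template(1L)
  r <- nicp_register(tmpl$mesh, tmpl$mesh, tmpl$landmarks, tmpl$landmarks)
  expect_lt(mean(r$per_vertex_distance), 1e-6)
  expect_identical(r$deformed_template$trilist, tmpl$mesh$trilist)
  expect_lt(max(abs(r$deformed_template$points - tmpl$mesh$points)), 1e-4)
})

test_that("a smooth low-frequency warp of a remeshed target is recovered", {
  tmpl <- tiny_template(1L)
  # the fundamental (half-period) displacement field at a typical
  # single-mode facial-variation amplitude
  f <- warped_target(tmpl, amplitudes = 2, seed = 11L)
  r <- nicp_register(tmpl$mesh, f$raw, tmpl$landmarks, f$landmarks)
  err <- sqrt(rowSums((r$deformed_template$points - f$gt)^2))
  expect_lt(mean(err), 0.05 * mean_edge_length(tmpl$mesh))
})

test_that("holes are filled by stiffness interpolation and flagged", {
  sp <- fixture_spec(n_subjects = 1L, seed = 11L, hole_probability = 1,
                     hole_radius = 18)
  pop <- generate_population(sp)
  s <- pop$subjects[[1L]]
  tmpl <- pop$template
  r <- nicp_register(tmpl$mesh, s$raw_mesh, tmpl$landmarks, s$landmarks_raw)
  gt_raw <- morphable3d:::apply_similarity(s$gt_mesh$points, s$rigid)
  inhole <- sqrt(rowSums(sweep(gt_raw, 2L, s$hole_center)^2)) < 14
  expect_gt(sum(inhole), 0L)
  expect_gt(sum(r$filled_mask & inhole), 0L)
  expect_true(all(is.finite(r$deformed_template$points)))
  # interpolated vertices stay within a few mm of the true surface they bridge
  expect_lt(mean(sqrt(rowSums((r$deformed_template$points[inhole, , drop = FALSE] -
                                 gt_raw[inhole, , drop = FALSE])^2))), 5)
})

test_that("fixed-correspondence energy never increases across inner solves", {
  tmpl <- tiny_template(0L)
  for (seed in c(4L, 9L)) {
    f <- warped_target(tmpl, amplitudes = c(2, -1.5, 1), seed = seed,
                       noise_sd = 0.15, raw_n_side = 13L)
    r <- nicp_register(tmpl$mesh, f$raw, tmpl$landmarks, f$landmarks,
                       trace = TRUE)
    expect_true(all(r$trace$energy_after <= r$trace$energy_before + 1e-8))
  }
})

test_that("very high stiffness pins the solution near one global affine", {
  tmpl <- tiny_template(0L)
  f <- warped_target(tmpl, amplitudes = c(3, 2), seed = 5L)
  spread <- sapply(c(1, 100, 10000), function(alpha) {
    cfg <- nicp_config(stiffness_schedule = c(alpha * 2, alpha),
                       landmark_schedule = c(1, 1))
    r <- nicp_register(tmpl$mesh, f$raw, tmpl$landmarks, f$landmarks,
                       config = cfg)
    X <- r$transforms$X
    blocks <- array(X, c(4L, nrow(X) / 4L, 3L))
    mean(apply(blocks, c(1L, 3L), stats::var))
  })
  expect_true(all(diff(spread) < 0))
})

test_that("registration inputs are validated", {
  tmpl <- tiny_template(0L)
  few <- landmark_set(tmpl$landmarks$labels[1:2],
                      tmpl$landmarks$points[1:2, , drop = FALSE],
                      template_indices = tmpl$landmarks$template_indices[1:2])
  few_t <- landmark_set(few$labels, few$points)
  expect_error(nicp_register(tmpl$mesh, tmpl$mesh, few, few_t),
               "at least 3")
  # disconnected template -> named singularity error
  disc <- triangle_mesh(matrix(rnorm(18), 6L, 3L),
                        rbind(c(1L, 2L, 3L), c(4L, 5L, 6L)))
  dl <- landmark_set(c("a", "b", "c"), disc$points[1:3, ],
                     template_indices = 1:3)
  dlt <- landmark_set(dl$labels, dl$points)
  expect_error(nicp_register(disc, tmpl$mesh, dl, dlt), "2 components")
  # landmark without template index
  no_idx <- landmark_set(tmpl$landmarks$labels, tmpl$landmarks$points)
  expect_error(
    nicp_energy(uniform_affine_stack(nrow(tmpl$mesh$points)), tmpl$mesh,
                tmpl$mesh, no_idx, no_idx, nicp_config(), 1, 1),
    "template_indices")
})

test_that("deformed output always carries the template topology", {
  tmpl <- tiny_template(0L)
  f <- warped_target(tmpl, amplitudes = 2, seed = 8L)
  r <- nicp_register(tmpl$mesh, f$raw, tmpl$landmarks, f$landmarks)
  expect_identical(r$deformed_template$trilist, tmpl$mesh$trilist)
  expect_true(all(r$per_vertex_distance >= 0))
})

test_that("registered-shape residuals are drift-dominated, not noise-dominated", {
  # register one subject surface under (a) two noise realizations and (b)
  # two remeshing realizations; the per-subject imprint of each nuisance is
  # near the noise scale, while the drift from ground truth is several times
  # larger — the structural limitation documented in the vignette
  tmpl <- tiny_template(1L)
  noise_sd <- 0.15
  fields <- morphable3d:::make_mode_fields(5L, tmpl$params)
  coef <- c(2, -1.5, 1, 0.8, -0.5)
  surface <- function(x, y) {
    p <- cbind(x, y, morphable3d:::face_height(x, y))
    for (j in 1:5) p <- p + coef[j] * fields[[j]](x, y)
    p
  }
  gt <- surface(tmpl$params[, 1L], tmpl$params[, 2L])
  lms <- landmark_set(tmpl$landmarks$labels,
                      gt[tmpl$landmarks$template_indices, , drop = FALSE])
  reg <- function(remesh_seed, noise_seed) {
    set.seed(remesh_seed)
    g <- morphable3d:::face_grid(21L, expand = 1.12)
    prm <- g$params
    dx <- diff(range(prm[, 1L])) / 20
    prm <- prm + cbind(runif(nrow(prm), -0.35, 0.35) * dx,
                       runif(nrow(prm), -0.35, 0.35) * dx)
    p <- surface(prm[, 1L], prm[, 2L])
    set.seed(noise_seed)
    raw <- triangle_mesh(p + matrix(rnorm(length(p), 0, noise_sd), ncol = 3L),
                         g$trilist, validate = FALSE)
    nicp_register(tmpl$mesh, raw, tmpl$landmarks, lms)$deformed_template$points
  }
  r11 <- reg(11L, 101L); r21 <- reg(22L, 101L); r12 <- reg(11L, 202L)
  imprint <- function(a, b) mean(sqrt(rowSums((a - b)^2))) / sqrt(2)
  noise_imprint <- imprint(r11, r12)
  remesh_imprint <- imprint(r11, r21)
  drift <- mean(sqrt(rowSums((r11 - gt)^2)))
  expect_lt(noise_imprint, 2 * noise_sd)
  expect_lt(remesh_imprint, 2 * noise_sd)
  expect_gt(drift, 2 * max(noise_imprint, remesh_imprint))
})
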