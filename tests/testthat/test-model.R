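test_that("similarity transforms are recovered exactly", {
  set.seed(1)
  X <- matrix(rnorm(30, sd = 8), 10L, 3L)
  expect_equal(procrustes_align(X, X)$s, 1, tolerance = 1e-12)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Y <- sweep(X %*% t(R) * 1.8, 2L, c(4, -2, 6), "+")
  tr <- procrustes_align(X, Y)
  expect_equal(tr$s, 1.8, tolerance = 1e-10)
  expect_equal(tr$R, R, tolerance = 1e-10)
  expect_lt(tr$residual, 1e-9)
  expect_equal(det(tr$R), 1, tolerance = 1e-10)
})

test_that("procrustes residual is at or below a dense grid search's", {
  set.seed(5)
  X <- matrix(rnorm(12, sd = 4), 4L, 3L)
  Y <- X * 1.2 + matrix(rnorm(12, sd = 0.8), 4L, 3L)
  best <- procrustes_align(X, Y)$residual
  # brute force over scale and z-rotation with optimal translation
  grid_best <- Inf
  for (s in seq(0.6, 2, length.out = 40L))
    for (th in seq(0, 2 * pi, length.out = 120L)) {
      R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
      Xp <- s * X %*% t(R)
      t0 <- colMeans(Y) - colMeans(Xp)
      r <- sqrt(mean(rowSums((sweep(Xp, 2L, t0, "+") - Y)^2)))
      grid_best <- min(grid_best, r)
    }
  expect_lte(best, grid_best + 1e-12)
})

test_that("degenerate configurations are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(procrustes_align(line, line), "rank")
  expect_error(procrustes_align(matrix(0, 4L, 3L), matrix(1, 4L, 3L)),
               "degenerate")
  expect_error(procrustes_align(matrix(0, 2L, 3L), matrix(0, 2L, 3L)),
               "3 points")
})

test_that("procrustes matches the vegan implementation on shared ground", {
  skip_if_not_installed("vegan")
  set.seed(9)
  X <- matrix(rnorm(30), 10L, 3L)
  Y <- X %*% diag(3L) * 1.5 + matrix(rnorm(30, sd = 0.3), 10L, 3L)
  ours <- procrustes_align(X, Y)
  vg <- vegan::procrustes(Y, X)  # rotates/scales X onto Y
  fitted_ours <- morphable3d:::apply_similarity(X, ours)
  expect_equal(sum((fitted_ours - Y)^2), sum(stats::resid(vg)^2),
               tolerance = 1e-8)
})

test_that("GPA aligns identical shapes under random similarities exactly", {
  set.seed(3)
  base <- tiny_template(0L)$mesh$points
  configs <- lapply(1:6, function(i) {
    th <- runif(1, 0, 2 * pi)
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    sweep(base %*% t(R) * runif(1, 0.5, 2), 2L, rnorm(3, sd = 20), "+")
  })
  g <- generalized_procrustes(configs)
  for (a in g$aligned)
    expect_lt(max(abs(a - g$mean)), 1e-6)
})

test_that("two-shape GPA mean agrees with the pairwise Procrustes midpoint", {
  set.seed(8)
  A <- matrix(rnorm(30, sd = 5), 10L, 3L)
  B <- A + matrix(rnorm(30, sd = 0.5), 10L, 3L)
  g <- generalized_procrustes(list(A, B), scale_to = "unit")
  # oracle: align B onto A directly; the mean shape is the midpoint
  trB <- procrustes_align(B, A)
  mid <- (A + morphable3d:::apply_similarity(B, trB)) / 2
  tr_mid <- procrustes_align(mid, g$mean)
  expect_lt(tr_mid$residual / centroid_size(g$mean), 1e-4)
})

test_that("single-mesh GPA returns the normalized shape unchanged", {
  mesh <- tiny_template(0L)$mesh
  g <- generalized_procrustes(list(mesh), scale_to = "unit")
  expect_equal(centroid_size(g$mean$points), 1, tolerance = 1e-9)
  expect_lt(max(abs(g$aligned[[1L]]$points - g$mean$points)), 1e-9)
  expect_error(generalized_procrustes(list()), "empty")
})

test_that("PCA matches the dense covariance eigendecomposition", {
  set.seed(2)
  X <- matrix(rnorm(5 * 12), 5L, 12L)
  m <- build_pca(X, variance_to_retain = 1)
  S <- stats::cov(X)
  ev <- eigen(S, symmetric = TRUE)
  d <- ncol(m$basis)
  expect_equal(m$eigenvalues, ev$values[seq_len(d)], tolerance = 1e-8)
  for (j in seq_len(d))
    expect_equal(abs(sum(m$basis[, j] * ev$vectors[, j])), 1,
                 tolerance = 1e-8)
  expect_equal(crossprod(m$basis), diag(d), tolerance = 1e-8)
})

test_that("rank-1 data yields a single perfect component", {
  set.seed(4)
  dir <- rnorm(9)
  X <- outer(rnorm(6L), dir) + rep(1, 6L) %o% rnorm(9)
  m <- build_pca(X, variance_to_retain = 0.999)
  expect_equal(ncol(m$basis), 1L)
  for (i in 1:6) {
    pr <- model_project(m, X[i, ])
    expect_lt(max(abs(pr$reconstruction - X[i, ])), 1e-8)
  }
})

test_that("full-variance models reconstruct training data exactly", {
  set.seed(6)
  X <- matrix(rnorm(8 * 15, sd = 3), 8L, 15L)
  m <- build_pca(X, variance_to_retain = 1)
  for (i in 1:8)
    expect_lt(max(abs(model_project(m, X[i, ])$reconstruction - X[i, ])), 1e-8)
})

test_that("projection equals the normal-equations least-squares solution", {
  set.seed(11)
  X <- matrix(rnorm(20 * 30), 20L, 30L)
  m <- build_pca(X, n_components = 6L)
  for (rep in 1:5) {
    x <- rnorm(30, sd = 2)
    pr <- model_project(m, x)
    ls <- qr.solve(m$basis, x - m$mean)  # generic LS oracle
    expect_equal(pr$coeffs, as.numeric(ls), tolerance = 1e-8)
    expect_equal(pr$reconstruction, m$mean + as.numeric(m$basis %*% ls),
                 tolerance = 1e-8)
  }
})

test_that("projection is idempotent and coefficients invert instances", {
  set.seed(12)
  X <- matrix(rnorm(10 * 18), 10L, 18L)
  m <- build_pca(X, n_components = 4L)
  expect_equal(model_project(m, m$mean)$coeffs, rep(0, 4L), tolerance = 1e-10)
  a0 <- rnorm(4L)
  inst <- model_instance(m, a0, as_mesh = FALSE)
  expect_equal(model_project(m, inst)$coeffs, a0, tolerance = 1e-10)
  p1 <- model_project(m, rnorm(18))$reconstruction
  expect_equal(model_project(m, p1)$reconstruction, p1, tolerance = 1e-10)
  expect_error(model_instance(m, rnorm(5L)), "coefficients")
  expect_error(model_project(m, rnorm(7L)), "length")
})

test_that("mode signs are deterministic across rebuilds", {
  set.seed(13)
  X <- matrix(rnorm(9 * 12), 9L, 12L)
  m1 <- build_pca(X, n_components = 3L)
  m2 <- build_pca(X[sample(9L), ], n_components = 3L)
  for (j in 1:3)
    expect_equal(abs(sum(m1$basis[, j] * m2$basis[, j])), 1, tolerance = 1e-8)
  expect_equal(m1$basis, m2$basis, tolerance = 1e-8)
})

test_that("random sampling follows the per-mode variances and the seed", {
  lam <- c(9, 4, 1)
  m <- morphable3d:::new_linear_model(rep(0, 12L), qr.Q(qr(matrix(rnorm(36), 12L))),
                                      lam, NULL, kind = "shape")
  s1 <- sample_model(m, seed = 42L)
  s2 <- sample_model(m, seed = 42L)
  expect_identical(s1$coeffs, s2$coeffs)
  draws <- t(sapply(1:10000, function(i) sample_model(m, seed = i)$coeffs))
  v <- apply(draws, 2L, stats::var)
  expect_lt(abs(v[1L] - lam[1L]) / lam[1L], 0.05)
  # all-zero eigenvalues always give the mean
  m0 <- morphable3d:::new_linear_model(rep(2, 12L), m$basis, c(0, 0, 0), NULL)
  expect_equal(sample_model(m0, seed = 1L)$instance, rep(2, 12L))
})

test_that("barycentric color transfer matches vertex colors and averages", {
  mesh <- triangle_mesh(rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0)),
                        matrix(1:3, 1L),
                        colors = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  expect_equal(transfer_color(mesh, mesh$points[2L, , drop = FALSE]),
               matrix(c(0, 1, 0), 1L), tolerance = 1e-9)
  cen <- matrix(colMeans(mesh$points), 1L)
  expect_equal(as.numeric(transfer_color(mesh, cen)), rep(1 / 3, 3L),
               tolerance = 1e-9)
  uni <- mesh; uni$colors <- matrix(0.4, 3L, 3L)
  set.seed(2)
  pts <- matrix(c(runif(5), runif(5), rep(0, 5L)), 5L)
  expect_true(all(abs(transfer_color(uni, pts) - 0.4) < 1e-9))
})

test_that("bespoke selection follows first-match rules with half-open ages", {
  dummy <- function(key) morphable3d:::new_linear_model(
    rep(0, 6L), diag(6L)[, 1L, drop = FALSE], 1, NULL,
    meta = list(key = key))
  keys <- c("global", vapply(default_bespoke_rules(), `[[`, "", "key"))
  models <- setNames(lapply(keys, dummy), keys)
  set_ <- bespoke_model_set(models)
  pick <- function(age, eth)
    select_bespoke(set_, list(age = age, ethnicity = eth), key_only = TRUE)
  expect_equal(pick(30, "White"), "white_18_to_50")
  expect_equal(pick(18, "White"), "white_18_to_50")  # half-open [18, 50)
  expect_equal(pick(7, "White"), "white_7_to_18")
  expect_equal(pick(3, "White"), "white_under_7")
  expect_equal(pick(80, "White"), "white_over_50")
  expect_equal(pick(12, "Black"), "black")
  expect_equal(pick(40, "Martian"), "global")
  expect_error(bespoke_model_set(models[-1L]), "fallback")
})

test_that("model archives round-trip bit-exactly", {
  set.seed(3)
  X <- matrix(rnorm(6 * 12), 6L, 12L)
  m <- build_pca(X, variance_to_retain = 0.99,
                 trilist = matrix(1:3, 1L), kind = "shape")
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  back <- load_model(f)
  expect_identical(back$mean, m$mean)
  expect_identical(back$basis, m$basis)
  expect_identical(back$eigenvalues, m$eigenvalues)
  expect_identical(back$trilist, m$trilist)
  saveRDS(1:3, f)
  expect_error(load_model(f), "model archive")
})
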