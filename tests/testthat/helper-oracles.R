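# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's own code paths: brute-force scans, dense grids, naive summation.

# cached small templates (built once per test run)
.tmpl_cache <- new.env()
tiny_template <- function(resolution = 0L) {
  key <- paste0("res", resolution)
  if (is.null(.tmpl_cache[[key]]))
    .tmpl_cache[[key]] <- make_template(resolution)
  .tmpl_cache[[key]]
}

random_mesh <- function(n = 12L, m = 15L, colors = FALSE, seed = 1L) {
  set.seed(seed)
  pts <- matrix(rnorm(3 * n, sd = 10), n, 3L)
  tri <- t(replicate(m, sample.int(n, 3L)))
  triangle_mesh(pts, tri,
                colors = if (colors) matrix(runif(3 * n), n, 3L) else NULL)
}

# Oracle: closest point on one triangle by dense barycentric grid search
# (refined), independent of the analytic Voronoi-region classification.
oracle_point_triangle <- function(p, a, b, c, steps = 200L) {
  u <- seq(0, 1, length.out = steps)
  grid <- expand.grid(l1 = u, l2 = u)
  grid <- grid[grid$l1 + grid$l2 <= 1, ]
  pts <- outer(grid$l1, a) + outer(grid$l2, b) + outer(1 - grid$l1 - grid$l2, c)
  pts <- matrix(pts, nrow(grid), 3L)
  d2 <- rowSums(sweep(pts, 2L, p)^2)
  sqrt(min(d2))
}

# Oracle: closest point over a whole mesh by exhaustive per-triangle grid
# search.
oracle_closest_distance <- function(p, mesh, steps = 120L) {
  t <- mesh$trilist
  min(vapply(seq_len(nrow(t)), function(i)
    oracle_point_triangle(p, mesh$points[t[i, 1L], ], mesh$points[t[i, 2L], ],
                          mesh$points[t[i, 3L], ], steps = steps),
    numeric(1L)))
}

# Oracle: registration energy by direct term-by-term summation (Eq.-style
# naive loops over vertices, edges, landmarks), using the grid-search
# closest distance.
oracle_nicp_energy <- function(stack, template, target, template_lms,
                               target_lms, gamma, alpha, beta, steps = 60L) {
  n <- nrow(template$points)
  E_d <- 0
  for (i in seq_len(n)) {
    A <- as_affine(stack, i)
    vhat <- as.numeric(A %*% c(template$points[i, ], 1))
    E_d <- E_d + oracle_closest_distance(vhat, target, steps = steps)^2
  }
  G <- diag(c(1, 1, 1, gamma))
  E_s <- 0
  e <- mesh_edges(template)
  for (r in seq_len(nrow(e))) {
    D <- (as_affine(stack, e[r, 1L]) - as_affine(stack, e[r, 2L])) %*% G
    E_s <- E_s + sum(D^2)
  }
  E_l <- 0
  common <- intersect(template_lms$labels, target_lms$labels)
  for (lab in common) {
    it <- match(lab, template_lms$labels)
    is <- match(lab, target_lms$labels)
    if (!template_lms$valid[it] || !target_lms$valid[is]) next
    k <- template_lms$template_indices[it]
    vhat <- as.numeric(as_affine(stack, k) %*% c(template$points[k, ], 1))
    E_l <- E_l + sum((vhat - target_lms$points[is, ])^2)
  }
  list(E = E_d + alpha * E_s + beta * E_l, E_d = E_d, E_s = E_s, E_l = E_l)
}

# Single-group, offset-free population spec: shape variation comes from the
# 5 Gaussian modes only (the "known linear model" conditions).
single_group_spec <- function(...) {
  demo1 <- data.frame(ethnicity = "White", proportion = 1, offset_scale = 0,
                      age_shape = 2, age_scale = 16)
  fixture_spec(demographics = demo1, ...)
}

# true mode-field matrix (3n x n_modes) at the template vertices
true_mode_matrix <- function(population) {
  tp <- population$template$params
  sapply(population$mode_fields, function(f)
    as.numeric(t(f(tp[, 1L], tp[, 2L]))))
}

principal_angles_deg <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  acos(pmin(1, svd(crossprod(qa, qb))$d)) * 180 / pi
}

# low-frequency warped + remeshed registration target with exact ground truth
warped_target <- function(template, amplitudes, seed = 3L, noise_sd = 0,
                          raw_n_side = 21L) {
  fields <- morphable3d:::make_mode_fields(length(amplitudes), template$params)
  surface <- function(x, y) {
    p <- cbind(x, y, morphable3d:::face_height(x, y))
    for (j in seq_along(amplitudes))
      p <- p + amplitudes[j] * fields[[j]](x, y)
    p
  }
  set.seed(seed)
  g <- morphable3d:::face_grid(raw_n_side, expand = 1.12)
  prm <- g$params
  dx <- diff(range(prm[, 1L])) / (raw_n_side - 1L)
  prm <- prm + cbind(runif(nrow(prm), -0.35, 0.35) * dx,
                     runif(nrow(prm), -0.35, 0.35) * dx)
  pts <- surface(prm[, 1L], prm[, 2L])
  if (noise_sd > 0)
    pts <- pts + matrix(rnorm(length(pts), 0, noise_sd), ncol = 3L)
  gt <- surface(template$params[, 1L], template$params[, 2L])
  lms <- landmark_set(template$landmarks$labels,
                      gt[template$landmarks$template_indices, , drop = FALSE])
  list(raw = triangle_mesh(pts, g$trilist, validate = FALSE),
       gt = gt, landmarks = lms)
}
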