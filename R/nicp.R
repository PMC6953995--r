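#' Per-vertex affine transform stack
#'
#' The unknowns of the non-rigid registration: one `3 x 4` affine transform
#' per template vertex, applied as `v_hat_i = A_i %*% c(v_i, 1)`. Stored
#' internally as a `4n x 3` matrix `X` whose `i`-th block of 4 rows is
#' `t(A_i)`, the layout in which the registration energy is a sparse linear
#' least-squares problem.
#'
#' @param X `4n x 3` numeric matrix.
#' @return an `affine_stack`.
#' @export
affine_stack <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) %% 4L != 0L || ncol(X) != 3L)
    stop("affine_stack: X must be a 4n x 3 matrix")
  if (!all(is.finite(X))) stop("affine_stack: non-finite entries")
  structure(list(X = X, n = nrow(X) %/% 4L), class = "affine_stack")
}

#' @rdname affine_stack
#' @param n number of template vertices.
#' @param s,R,t optional similarity used to initialize every per-vertex
#'   transform (defaults to the identity).
#' @export
uniform_affine_stack <- function(n, s = 1, R = diag(3L), t = c(0, 0, 0)) {
  block <- rbind(t(s * R), t)  # 4 x 3 == t([sR | t])
  affine_stack(block[rep(seq_len(4L), n), , drop = FALSE])
}

#' @rdname affine_stack
#' @param stack an `affine_stack`.
#' @param i vertex index.
#' @return `as_affine(stack, i)`: the `3 x 4` matrix `A_i`.
#' @export
as_affine <- function(stack, i) {
  t(stack$X[(4L * (i - 1L) + 1L):(4L * i), , drop = FALSE])
}

#' @export
print.affine_stack <- function(x, ...) {
  cat(sprintf("affine_stack: %d per-vertex 3x4 affine transforms\n", x$n))
  invisible(x)
}

# Sparse n x 4n design matrix with row i = (v_i, 1) in columns 4(i-1)+1..4i,
# so that (D %*% X)[i, ] is the deformed position of vertex i.
nicp_design <- function(points) {
  n <- nrow(points)
  Matrix::sparseMatrix(
    i = rep(seq_len(n), each = 4L),
    j = seq_len(4L * n),
    x = as.numeric(t(cbind(points, 1))),
    dims = c(n, 4L * n))
}

# Sparse 4|E| x 4n stiffness operator: node-arc incidence kron G, with
# G = diag(1, 1, 1, gamma) weighting translation differences by gamma.
nicp_stiffness_operator <- function(edges, n, gamma) {
  ne <- nrow(edges)
  M <- Matrix::sparseMatrix(
    i = rep(seq_len(ne), 2L),
    j = c(edges[, 1L], edges[, 2L]),
    x = rep(c(1, -1), each = ne),
    dims = c(ne, n))
  Matrix::kronecker(M, Matrix::Diagonal(4L, c(1, 1, 1, gamma)))
}

#' Configuration for non-rigid ICP registration
#'
#' The registration anneals a stiffness weight `alpha` over an outer schedule
#' (high stiffness first: near-global affine; low stiffness last: local
#' detail), with a landmark weight `beta` that guides the early iterations
#' and releases at the end. `gamma` balances translational versus
#' rotational/skew differences in the stiffness term.
#'
#' @param stiffness_schedule strictly decreasing positive `alpha` values.
#' @param landmark_schedule non-negative `beta` values, same length.
#' @param gamma positive scalar weighting the translation column.
#' @param inner_tolerance mean vertex displacement (mm) terminating the inner
#'   loop.
#' @param max_inner_iters inner-iteration cap per stiffness level.
#' @param normal_compatibility_deg maximum angle (degrees) between the
#'   deformed-template vertex normal and the target surface normal for a
#'   correspondence to be kept.
#' @param max_correspondence_dist distance cap (mm) for correspondences;
#'   `NULL` means 5x the mean template edge length, resolved at registration
#'   time.
#' @return an object of class `nicp_config`.
#' @export
nicp_config <- function(stiffness_schedule = geometric_schedule(50, 0.5, 8L),
                        landmark_schedule = seq(5, 0, length.out = 8L),
                        gamma = 1,
                        inner_tolerance = 0.1,
                        max_inner_iters = 10L,
                        normal_compatibility_deg = 60,
                        max_correspondence_dist = NULL) {
  if (length(stiffness_schedule) != length(landmark_schedule))
    stop("nicp_config: schedules must have the same length")
  if (any(stiffness_schedule <= 0) || any(diff(stiffness_schedule) >= 0))
    stop("nicp_config: stiffness_schedule must be strictly decreasing and positive")
  if (any(landmark_schedule < 0))
    stop("nicp_config: landmark_schedule must be non-negative")
  stopifnot(gamma > 0, inner_tolerance > 0, max_inner_iters >= 1L,
            normal_compatibility_deg > 0,
            is.null(max_correspondence_dist) || max_correspondence_dist > 0)
  structure(list(stiffness_schedule = as.numeric(stiffness_schedule),
                 landmark_schedule = as.numeric(landmark_schedule),
                 gamma = gamma, inner_tolerance = inner_tolerance,
                 max_inner_iters = as.integer(max_inner_iters),
                 normal_compatibility_deg = normal_compatibility_deg,
                 max_correspondence_dist = max_correspondence_dist),
            class = "nicp_config")
}

#' @rdname nicp_config
#' @param from,to,n geometric schedule endpoints and length.
#' @export
geometric_schedule <- function(from, to, n) {
  exp(seq(log(from), log(to), length.out = n))
}

# Match template-attached landmarks to target landmarks by label; keeps
# labels valid in both sets. Returns template vertex indices and target
# points.
match_landmarks <- function(template_landmarks, target_landmarks) {
  if (is.null(template_landmarks$template_indices))
    stop("template landmarks must carry template_indices")
  common <- intersect(template_landmarks$labels, target_landmarks$labels)
  it <- match(common, template_landmarks$labels)
  is <- match(common, target_landmarks$labels)
  ok <- template_landmarks$valid[it] & target_landmarks$valid[is]
  list(labels = common[ok],
       k = template_landmarks$template_indices[it[ok]],
       L = target_landmarks$points[is[ok], , drop = FALSE])
}

#' Registration energy and its terms
#'
#' Evaluates the non-rigid registration energy
#' `E = E_d + alpha * E_s + beta * E_l`: the data term sums squared
#' point-to-surface distances of the deformed template vertices; the
#' stiffness term sums squared Frobenius norms of gamma-weighted differences
#' of neighbouring transforms over the template edge set; the landmark term
#' sums squared distances of deformed landmark vertices to their target
#' locations.
#'
#' @param transforms an `affine_stack` (one transform per template vertex).
#' @param template,target `triangle_mesh` objects.
#' @param template_landmarks landmark set with `template_indices`.
#' @param target_landmarks landmark set with 3D points on the target.
#' @param config an [nicp_config()] (supplies `gamma`).
#' @param alpha,beta term weights.
#' @return list with `E`, `E_d`, `E_s`, `E_l`.
#' @export
nicp_energy <- function(transforms, template, target,
                        template_landmarks, target_landmarks,
                        config, alpha, beta) {
  n <- nrow(template$points)
  if (transforms$n != n)
    stop("nicp_energy: transform count != template vertex count")
  D <- nicp_design(template$points)
  Vhat <- as.matrix(D %*% transforms$X)
  E_d <- sum(closest_point_on_surface(Vhat, target)$distance^2)
  MG <- nicp_stiffness_operator(mesh_edges(template), n, config$gamma)
  E_s <- sum((MG %*% transforms$X)^2)
  lm <- match_landmarks(template_landmarks, target_landmarks)
  E_l <- if (length(lm$k))
    sum((Vhat[lm$k, , drop = FALSE] - lm$L)^2) else 0
  list(E = E_d + alpha * E_s + beta * E_l, E_d = E_d, E_s = E_s, E_l = E_l)
}

#' Landmark-guided non-rigid ICP registration of a template to a scan
#'
#' Deforms the template (one affine transform per vertex) to match the target
#' surface. After an initial landmark-driven similarity alignment
#' (Procrustes), the method anneals the stiffness weight over
#' `config$stiffness_schedule`; at each level it alternates (i) closest-point
#' correspondence search from the current deformed vertices — dropping
#' correspondences that are too distant, land on a target boundary, or whose
#' normals disagree — with (ii) an exact sparse least-squares solve for all
#' transforms given those correspondences (the "optimal step"). Template
#' vertices without a valid correspondence at the final stiffness level are
#' positioned by the stiffness term alone, which interpolates smoothly across
#' holes in the scan; they are reported in `filled_mask`.
#'
#' @param template `triangle_mesh` (the deformable surface; must be
#'   edge-connected).
#' @param target `triangle_mesh` (the raw scan).
#' @param template_landmarks landmark set with `template_indices`.
#' @param target_landmarks landmark set with 3D points; at least 3 labels
#'   must be valid in both sets.
#' @param config an [nicp_config()].
#' @param trace record per-solve fixed-correspondence energies (for
#'   convergence diagnostics).
#' @return a `registration_result`: `deformed_template` (template topology;
#'   colors sampled from the target when present), `transforms`
#'   (`affine_stack`), `per_vertex_distance` (mm), `filled_mask`,
#'   `final_energy`, `initial_alignment`, and optionally `trace` (data frame
#'   with columns `level`, `iter`, `energy_before`, `energy_after`).
#' @export
nicp_register <- function(template, target, template_landmarks,
                          target_landmarks, config = nicp_config(),
                          trace = FALSE) {
  validate_mesh(template); validate_mesh(target)
  lm <- match_landmarks(template_landmarks, target_landmarks)
  if (length(lm$k) < 3L)
    stop("nicp_register: at least 3 mutually valid landmarks required (got ",
         length(lm$k), ")")
  comp <- vertex_components(template)
  if (max(comp) > 1L)
    stop("nicp_register: template vertex graph is disconnected (",
         max(comp), " components with sizes ",
         paste(tabulate(comp), collapse = ", "),
         "); the stiffness system would be singular")

  n <- nrow(template$points)
  max_dist <- config$max_correspondence_dist
  if (is.null(max_dist)) max_dist <- 5 * mean_edge_length(template)
  cos_thresh <- cos(config$normal_compatibility_deg * pi / 180)

  # initial similarity alignment of the template onto the target landmarks
  init <- procrustes_align(template$points[lm$k, , drop = FALSE], lm$L,
                           allow_scale = TRUE)
  X <- uniform_affine_stack(n, s = init$s, R = init$R, t = init$t)$X

  D <- nicp_design(template$points)
  Dt <- Matrix::t(D)
  DL <- D[lm$k, , drop = FALSE]
  DLtDL <- Matrix::crossprod(DL)
  DLtL <- Matrix::crossprod(DL, lm$L)
  MG <- nicp_stiffness_operator(mesh_edges(template), n, config$gamma)
  MtM <- Matrix::crossprod(MG)

  # target boundary structure for correspondence rejection
  tgt_boundary_v <- boundary_vertices(target)
  cnt <- edge_counts(target)
  tgt_boundary_edges <- names(cnt)[cnt == 1L]
  tgt_tri_normals <- triangle_normals(target)
  tmesh_tl <- template$trilist

  fixed_energy <- function(Xm, w, U, alpha, beta) {
    Vh <- as.matrix(D %*% Xm)
    sum(w * rowSums((Vh - U)^2)) + alpha * sum((MG %*% Xm)^2) +
      (if (beta > 0) beta * sum((Vh[lm$k, , drop = FALSE] - lm$L)^2) else 0)
  }

  trace_rows <- list()
  w <- rep(1, n)
  for (level in seq_along(config$stiffness_schedule)) {
    alpha <- config$stiffness_schedule[level]
    beta <- config$landmark_schedule[level]
    for (iter in seq_len(config$max_inner_iters)) {
      Vhat <- as.matrix(D %*% X)
      cp <- closest_point_on_surface(Vhat, target)
      w <- rep(1, n)
      w[cp$distance > max_dist] <- 0
      w[on_target_boundary(cp, target$trilist, tgt_boundary_v,
                           tgt_boundary_edges)] <- 0
      vn <- vertex_normals(triangle_mesh(Vhat, tmesh_tl, validate = FALSE))
      compat <- rowSums(vn * tgt_tri_normals[cp$triangle, , drop = FALSE])
      w[compat < cos_thresh] <- 0
      U <- cp$point

      lhs <- alpha * MtM + Matrix::crossprod(D * sqrt(w))
      rhs <- Dt %*% (U * w)
      if (beta > 0) {
        lhs <- lhs + beta * DLtDL
        rhs <- rhs + beta * DLtL
      }
      X_new <- tryCatch(
        as.matrix(Matrix::solve(lhs, rhs)),
        error = function(e)
          stop("nicp_register: singular registration system (", conditionMessage(e), ")"))
      if (trace) {
        trace_rows[[length(trace_rows) + 1L]] <- data.frame(
          level = level, iter = iter,
          energy_before = fixed_energy(X, w, U, alpha, beta),
          energy_after = fixed_energy(X_new, w, U, alpha, beta))
      }
      displacement <- mean(sqrt(rowSums((as.matrix(D %*% X_new) - Vhat)^2)))
      X <- X_new
      if (displacement < config$inner_tolerance) break
    }
  }

  Vhat <- as.matrix(D %*% X)
  cp <- closest_point_on_surface(Vhat, target)
  stack <- affine_stack(X)
  colors <- if (!is.null(target$colors))
    transfer_color(target, Vhat, triangle = cp$triangle, bary = cp$bary)
  deformed <- triangle_mesh(Vhat, tmesh_tl, colors = colors, validate = FALSE)
  fe <- nicp_energy(stack, template, target, template_landmarks,
                    target_landmarks, config,
                    alpha = config$stiffness_schedule[length(config$stiffness_schedule)],
                    beta = config$landmark_schedule[length(config$landmark_schedule)])
  out <- list(deformed_template = deformed,
              transforms = stack,
              per_vertex_distance = cp$distance,
              filled_mask = w == 0,
              final_energy = fe$E,
              initial_alignment = init)
  if (trace) out$trace <- do.call(rbind, trace_rows)
  class(out) <- "registration_result"
  out
}

# Correspondences whose foot point lies on a boundary vertex or boundary edge
# of the target are unreliable (the true surface continues past the rim).
on_target_boundary <- function(cp, trilist, boundary_v, boundary_edge_keys,
                               eps = 1e-9) {
  tri <- trilist[cp$triangle, , drop = FALSE]
  b <- cp$bary
  nz <- b > eps
  nnz <- rowSums(nz)
  out <- logical(nrow(b))
  # foot at a vertex: the single active barycentric coordinate
  at_vertex <- nnz == 1L
  if (any(at_vertex)) {
    vid <- tri[cbind(which(at_vertex),
                     max.col(nz[at_vertex, , drop = FALSE], "first"))]
    out[at_vertex] <- boundary_v[vid]
  }
  # foot on an edge: the two active coordinates
  on_edge <- nnz == 2L
  if (any(on_edge)) {
    rows <- which(on_edge)
    zero_col <- max.col(!nz[rows, , drop = FALSE], "first")
    other <- rbind(c(2L, 3L), c(1L, 3L), c(1L, 2L))
    v1 <- tri[cbind(rows, other[zero_col, 1L])]
    v2 <- tri[cbind(rows, other[zero_col, 2L])]
    key <- paste(pmin(v1, v2), pmax(v1, v2))
    out[rows] <- key %in% boundary_edge_keys
  }
  out
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "registration_result: %d vertices, mean surface distance %.4g mm, %d hole-filled, final energy %.4g\n",
    length(x$per_vertex_distance), mean(x$per_vertex_distance),
    sum(x$filled_mask), x$final_energy))
  invisible(x)
}

#' Persist a registration result as PLY plus JSON sidecar
#'
#' Writes the deformed template as PLY and a JSON sidecar carrying the
#' configuration echo, final energy, hole-fill mask and per-vertex distances.
#'
#' @param result a `registration_result`.
#' @param path output PLY path; the sidecar is `<path>.json`.
#' @param config the [nicp_config()] used (echoed into the sidecar).
#' @export
write_registration <- function(result, path, config = NULL) {
  write_mesh(result$deformed_template, path, format = "ply")
  side <- list(final_energy = result$final_energy,
               filled_mask = result$filled_mask,
               per_vertex_distance = result$per_vertex_distance,
               config = if (!is.null(config)) unclass(config))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
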