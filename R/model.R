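#' Linear (PCA) shape or texture model
#'
#' A morphable model component: mean vector, orthonormal basis of modes, and
#' per-mode variances (eigenvalues of the training covariance), plus the
#' shared triangulation. Novel instances are `mean + basis %*% coeffs`; any
#' input is projected onto the model subspace by
#' `coeffs = t(basis) %*% (x - mean)`.
#'
#' @name linear_model
NULL

new_linear_model <- function(mean, basis, eigenvalues, trilist,
                             kind = c("shape", "texture"),
                             all_eigenvalues = eigenvalues, n_train = NA_integer_,
                             meta = list()) {
  kind <- match.arg(kind)
  structure(list(mean = as.numeric(mean), basis = as.matrix(basis),
                 eigenvalues = as.numeric(eigenvalues),
                 all_eigenvalues = as.numeric(all_eigenvalues),
                 trilist = trilist, kind = kind,
                 n_train = as.integer(n_train), meta = meta),
            class = "linear_model")
}

#' @export
print.linear_model <- function(x, ...) {
  cat(sprintf("linear_model (%s): %d modes over %d-dim vectors (%d training samples)\n",
              x$kind, ncol(x$basis), length(x$mean), x$n_train))
  if (length(x$all_eigenvalues))
    cat(sprintf("  retained variance: %.2f%%\n",
                100 * sum(x$eigenvalues) / sum(x$all_eigenvalues)))
  invisible(x)
}

#' Build a PCA model from corresponded sample vectors
#'
#' Computes the sample mean and the principal modes of variation via thin
#' singular-value decomposition of the centered `k x 3n` data matrix (the
#' `3n x 3n` covariance is never materialized, so the construction scales to
#' dense meshes). Eigenvalues are the variances of the training data along
#' each mode (`sigma^2 / (k - 1)`). Mode signs are fixed by making each
#' column's largest-magnitude entry positive, so builds are reproducible
#' across platforms.
#'
#' @param samples `k x 3n` numeric matrix (one flattened shape or texture
#'   vector per row), or a list of corresponded `triangle_mesh` objects.
#' @param variance_to_retain fraction of total variance the truncated model
#'   must explain (default `0.995`); ignored when `n_components` is given.
#' @param n_components retain exactly this many modes.
#' @param trilist shared topology (taken from the meshes when a list is given).
#' @param kind `"shape"` or `"texture"`.
#' @return a `linear_model`.
#' @export
build_pca <- function(samples, variance_to_retain = 0.995, n_components = NULL,
                      trilist = NULL, kind = "shape") {
  if (is.list(samples) && inherits(samples[[1L]], "triangle_mesh")) {
    trilist <- samples[[1L]]$trilist
    samples <- do.call(rbind, lapply(samples, as_shape_vector))
  }
  samples <- as.matrix(samples)
  k <- nrow(samples)
  if (k < 2L) stop("build_pca: at least 2 samples required")
  mu <- colMeans(samples)
  Xc <- sweep(samples, 2L, mu)
  sv <- svd(Xc, nu = 0L)
  lambda <- sv$d^2 / (k - 1)
  # numerically-zero modes carry no variance; drop them (d <= k - 1)
  keep_nz <- lambda > max(lambda[1L], .Machine$double.eps) * 1e-12
  if (k <= length(lambda))
    keep_nz[k] <- FALSE  # centering makes the k-th singular value exactly 0
  lambda_all <- lambda[keep_nz]
  V <- sv$v[, keep_nz, drop = FALSE]
  d <- if (!is.null(n_components)) {
    if (n_components < 1L || n_components > length(lambda_all))
      stop("build_pca: n_components must be in [1, ", length(lambda_all), "]")
    as.integer(n_components)
  } else {
    if (variance_to_retain <= 0 || variance_to_retain > 1)
      stop("build_pca: variance_to_retain must be in (0, 1]")
    cum <- cumsum(lambda_all) / sum(lambda_all)
    which(cum >= variance_to_retain - 1e-12)[1L]
  }
  V <- V[, seq_len(d), drop = FALSE]
  # sign convention: largest-magnitude entry of each mode is positive
  flip <- vapply(seq_len(d), function(j) {
    col <- V[, j]
    sign(col[which.max(abs(col))])
  }, numeric(1L))
  V <- sweep(V, 2L, flip, "*")
  new_linear_model(mu, V, lambda_all[seq_len(d)], trilist, kind = kind,
                   all_eigenvalues = lambda_all, n_train = k,
                   meta = list(variance_to_retain =
                                 if (is.null(n_components)) variance_to_retain else NA,
                               n_components = d))
}

#' Generate a model instance from coefficients
#'
#' `x = mean + basis %*% coeffs`. Coefficient vectors shorter than the number
#' of modes are zero-padded (truncated-model instance).
#'
#' @param model a `linear_model`.
#' @param coeffs numeric vector, `length(coeffs) <= ncol(basis)`.
#' @param as_mesh return a `triangle_mesh` on the shared topology (shape
#'   models only; default `TRUE` when a trilist is available).
#' @return a `triangle_mesh` or a numeric vector.
#' @export
model_instance <- function(model, coeffs,
                           as_mesh = model$kind == "shape" && !is.null(model$trilist)) {
  d <- ncol(model$basis)
  if (length(coeffs) > d)
    stop("model_instance: ", length(coeffs), " coefficients for ", d, " modes")
  cf <- numeric(d)
  cf[seq_along(coeffs)] <- coeffs
  x <- model$mean + as.numeric(model$basis %*% cf)
  if (as_mesh) shape_vector_to_mesh(x, model$trilist) else x
}

#' Project a vector onto the model subspace
#'
#' Orthogonal (least-squares) projection: `coeffs = t(U) (x - mean)` and
#' `P(x) = mean + U coeffs`, optionally truncated to the leading
#' `n_components` modes.
#'
#' @param model a `linear_model`.
#' @param x length-`3n` numeric vector or a corresponded `triangle_mesh`.
#' @param n_components truncate the projection to this many leading modes.
#' @return list with `coeffs` and `reconstruction` (numeric vector).
#' @export
model_project <- function(model, x, n_components = NULL) {
  if (inherits(x, "triangle_mesh")) x <- as_shape_vector(x)
  if (length(x) != length(model$mean))
    stop("model_project: vector length ", length(x), " != model dimension ",
         length(model$mean))
  U <- model$basis
  if (!is.null(n_components)) {
    if (n_components > ncol(U))
      stop("model_project: n_components exceeds available modes")
    U <- U[, seq_len(n_components), drop = FALSE]
  }
  a <- as.numeric(crossprod(U, x - model$mean))
  list(coeffs = a, reconstruction = model$mean + as.numeric(U %*% a))
}

#' Sample a random instance from the model's Gaussian
#'
#' Coefficients are drawn independently as `alpha_i ~ N(0, lambda_i)` —
#' the probabilistic reading of the PCA model. Deterministic for a fixed
#' seed.
#'
#' @param model a `linear_model`.
#' @param n_components restrict sampling to the leading modes.
#' @param seed optional integer seed (uses and restores the local RNG stream
#'   via a private state when given).
#' @return list with `coeffs` and `instance` (numeric vector).
#' @export
sample_model <- function(model, n_components = ncol(model$basis), seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  lam <- model$eigenvalues[seq_len(n_components)]
  a <- stats::rnorm(n_components, mean = 0, sd = sqrt(pmax(lam, 0)))
  list(coeffs = a,
       instance = model_instance(model, a, as_mesh = FALSE))
}

#' Barycentric color transfer from a colored surface
#'
#' Samples the source mesh's per-vertex color field at arbitrary surface
#' points: each point's color is the barycentric combination of its triangle's
#' vertex colors (clamped to `[0, 1]`). Points not supplied with a location
#' are located with [closest_point_on_surface()].
#'
#' @param source a `triangle_mesh` with colors.
#' @param points `q x 3` matrix of points on (or near) the source surface.
#' @param triangle,bary optional precomputed locations (as returned by
#'   [closest_point_on_surface()]).
#' @return `q x 3` matrix of colors in `[0, 1]`.
#' @export
transfer_color <- function(source, points, triangle = NULL, bary = NULL) {
  if (is.null(source$colors)) stop("transfer_color: source mesh has no colors")
  if (is.null(triangle) || is.null(bary)) {
    loc <- closest_point_on_surface(points, source)
    triangle <- loc$triangle; bary <- loc$bary
  }
  t <- source$trilist[triangle, , drop = FALSE]
  cl <- source$colors[t[, 1L], , drop = FALSE] * bary[, 1L] +
        source$colors[t[, 2L], , drop = FALSE] * bary[, 2L] +
        source$colors[t[, 3L], , drop = FALSE] * bary[, 3L]
  pmin(pmax(cl, 0), 1)
}

## ---- demographically bespoke model collections ----

#' Bespoke (demographic-specific) model collection
#'
#' An ordered rule list mapping demographic records to dedicated sub-models,
#' with a global fallback. The default rule set mirrors the six-group layout
#' used for large face-model cohorts: Black (all ages), Chinese (all ages),
#' and the White group split at ages 7, 18 and 50 into four bands, with the
#' half-open convention `[lower, upper)`.
#'
#' @param models named list of `linear_model`s; must contain `fallback_key`.
#' @param rules list of rules, each
#'   `list(key=, ethnicity=NULL, age_min=0, age_max=Inf)`; a record matches the
#'   first rule whose ethnicity (if any) equals the record's and whose age lies
#'   in `[age_min, age_max)`.
#' @param fallback_key name of the global model (default `"global"`).
#' @return a `bespoke_model_set`.
#' @export
bespoke_model_set <- function(models, rules = default_bespoke_rules(),
                              fallback_key = "global") {
  if (!fallback_key %in% names(models))
    stop("bespoke_model_set: fallback key '", fallback_key, "' not in models")
  keys <- vapply(rules, `[[`, "", "key")
  missing_keys <- setdiff(keys, names(models))
  if (length(missing_keys))
    stop("bespoke_model_set: rule keys without models: ",
         paste(missing_keys, collapse = ", "))
  structure(list(models = models, rules = rules, fallback_key = fallback_key),
            class = "bespoke_model_set")
}

#' @rdname bespoke_model_set
#' @param age_edges age band edges for the White group (half-open bins).
#' @export
default_bespoke_rules <- function(age_edges = c(7, 18, 50)) {
  e <- age_edges
  list(
    list(key = "black", ethnicity = "Black", age_min = 0, age_max = Inf),
    list(key = "chinese", ethnicity = "Chinese", age_min = 0, age_max = Inf),
    list(key = "white_under_7", ethnicity = "White", age_min = 0, age_max = e[1L]),
    list(key = "white_7_to_18", ethnicity = "White", age_min = e[1L], age_max = e[2L]),
    list(key = "white_18_to_50", ethnicity = "White", age_min = e[2L], age_max = e[3L]),
    list(key = "white_over_50", ethnicity = "White", age_min = e[3L], age_max = Inf))
}

#' Select the bespoke model matching a demographic record
#'
#' First-match rule semantics with age bins half-open `[age_min, age_max)`;
#' records matching no rule get the global fallback model.
#'
#' @param set a [bespoke_model_set()].
#' @param record one-row `demographic_records` (or a list with `age`,
#'   `ethnicity`).
#' @param key_only return the model key instead of the model.
#' @return a `linear_model` (or its key).
#' @export
select_bespoke <- function(set, record, key_only = FALSE) {
  age <- as.numeric(record$age)
  eth <- as.character(record$ethnicity)
  key <- set$fallback_key
  for (rule in set$rules) {
    eth_ok <- is.null(rule$ethnicity) || identical(rule$ethnicity, eth)
    if (eth_ok && age >= rule$age_min && age < rule$age_max) {
      key <- rule$key
      break
    }
  }
  if (key_only) key else set$models[[key]]
}

## ---- persistence ----

#' Save / load a linear model archive
#'
#' The archive holds mean, basis, eigenvalues (retained and full spectrum),
#' the shared trilist and a metadata block (kind, truncation rule, training
#' count). Serialized with R's native format for a bit-exact round trip.
#'
#' @param model a `linear_model` (or a `bespoke_model_set`).
#' @param path file path (conventionally `.rds`).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, c("linear_model", "bespoke_model_set")))
    stop("load_model: file does not contain a model archive: ", path)
  obj
}
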