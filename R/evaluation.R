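# Intrinsic and fitting evaluation of morphable models: compactness,
# generalization and specificity curves, the nearest-vertex fitting protocol
# with radial cropping and cumulative error distributions, and an
# age-classification demonstration of the descriptive power of the shape
# coefficients.

#' Evaluation curve container
#'
#' @param x strictly increasing abscissa (components retained, % variance, or
#'   an error threshold in mm).
#' @param y metric values (same length, finite).
#' @param metric metric name.
#' @param model_key identifier of the evaluated model.
#' @return a `curve_result` (also a data frame).
#' @export
curve_result <- function(x, y, metric, model_key = "global") {
  if (length(x) != length(y)) stop("curve_result: x/y length mismatch")
  if (any(diff(x) <= 0)) stop("curve_result: x must be strictly increasing")
  if (any(!is.finite(y))) stop("curve_result: non-finite metric value")
  structure(data.frame(x = x, y = y),
            metric = metric, model_key = model_key,
            class = c("curve_result", "data.frame"))
}

#' @export
print.curve_result <- function(x, ...) {
  cat(sprintf("curve_result [%s, model %s]: %d points, y in [%.4g, %.4g]\n",
              attr(x, "metric"), attr(x, "model_key"), nrow(x),
              min(x$y), max(x$y)))
  invisible(x)
}

#' Write / plot an evaluation curve
#' @param curve a `curve_result`.
#' @param path output file (`.csv`, or `.png`/`.svg` for the plot).
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(data.frame(x = curve$x, y = curve$y,
                              metric = attr(curve, "metric"),
                              model = attr(curve, "model_key")),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
plot_curve <- function(curve, path = NULL) {
  draw <- function() {
    graphics::plot(curve$x, curve$y, type = "b", pch = 16,
                   xlab = "x", ylab = attr(curve, "metric"),
                   main = sprintf("%s (%s)", attr(curve, "metric"),
                                  attr(curve, "model_key")))
    graphics::grid()
  }
  if (is.null(path)) {
    draw()
  } else {
    ext <- tolower(tools::file_ext(path))
    switch(ext,
           png = grDevices::png(path, width = 800, height = 600),
           svg = grDevices::svg(path, width = 8, height = 6),
           stop("plot_curve: unsupported extension '", ext, "'"))
    on.exit(grDevices::dev.off())
    draw()
  }
  invisible(path)
}

#' Model compactness curve
#'
#' Percentage of training-set variance explained when `c` principal
#' components are retained: `y(c) = 100 * sum_{i<=c} lambda_i / sum_i
#' lambda_i`, computed over the model's full (untruncated) spectrum.
#'
#' @param model a `linear_model`, or a numeric vector of eigenvalues.
#' @param model_key label for the curve.
#' @return a [curve_result()] over `c = 1 .. d`.
#' @export
compactness_curve <- function(model, model_key = "global") {
  lam <- if (inherits(model, "linear_model")) model$all_eigenvalues else
    as.numeric(model)
  curve_result(seq_along(lam), 100 * cumsum(lam) / sum(lam),
               metric = "compactness_pct", model_key = model_key)
}

# mean over vertices of per-vertex Euclidean distance between two flattened
# shape vectors
mean_pervertex_dist <- function(a, b) {
  d <- matrix(a - b, ncol = 3L, byrow = TRUE)
  mean(sqrt(rowSums(d^2)))
}

#' Model generalization curve
#'
#' Ability to represent unseen shapes: for each number of retained
#' components `c`, every test shape is projected onto the truncated model
#' and the per-vertex Euclidean distance to its projection is averaged over
#' all vertices and all test shapes. Test shapes must share the model
#' topology and be aligned to the model frame. With a
#' [bespoke_model_set()] and demographic `records`, each test shape is
#' routed to its demographically matching sub-model.
#'
#' @param model a `linear_model` or a `bespoke_model_set`.
#' @param test_shapes `k x 3n` matrix or list of corresponded meshes.
#' @param components abscissa; defaults to `1 .. d` (capped per sub-model in
#'   bespoke mode).
#' @param records `demographic_records` aligned with `test_shapes` (bespoke
#'   mode only).
#' @param model_key label.
#' @return a [curve_result()] in mm.
#' @export
generalization_curve <- function(model, test_shapes, components = NULL,
                                 records = NULL, model_key = "global") {
  if (is.list(test_shapes) && inherits(test_shapes[[1L]], "triangle_mesh"))
    test_shapes <- do.call(rbind, lapply(test_shapes, as_shape_vector))
  test_shapes <- as.matrix(test_shapes)
  k <- nrow(test_shapes)
  bespoke <- inherits(model, "bespoke_model_set")
  if (bespoke && (is.null(records) || nrow(records) != k))
    stop("generalization_curve: bespoke mode needs one demographic record per test shape")
  if (!bespoke && length(model$mean) != ncol(test_shapes))
    stop("generalization_curve: test shapes do not match the model topology")
  dmax <- if (bespoke)
    max(vapply(model$models, function(m) ncol(m$basis), integer(1L)))
  else ncol(model$basis)
  if (is.null(components)) components <- seq_len(dmax)
  y <- vapply(components, function(cc) {
    errs <- vapply(seq_len(k), function(i) {
      m <- if (bespoke) select_bespoke(model, records[i, ]) else model
      ci <- min(cc, ncol(m$basis))
      pr <- model_project(m, test_shapes[i, ], n_components = ci)
      mean_pervertex_dist(test_shapes[i, ], pr$reconstruction)
    }, numeric(1L))
    mean(errs)
  }, numeric(1L))
  curve_result(components, y, metric = "generalization_mm",
               model_key = model_key)
}

#' Model specificity
#'
#' Realism of the model's synthetic output: faces are sampled from the
#' model's Gaussian (truncated at `n_components`) and each is compared with
#' its nearest neighbour in the test set, in terms of the average per-vertex
#' distance; the mean and standard deviation of that nearest-neighbour
#' distance over all samples is returned.
#'
#' @param model a `linear_model`.
#' @param test_shapes `k x 3n` matrix or list of corresponded meshes.
#' @param n_samples number of random synthetic faces (default 10000).
#' @param n_components modes used when sampling.
#' @param seed RNG seed for the synthetic draws.
#' @return list with `mean`, `sd`, and the per-sample `distances` (mm).
#' @export
specificity <- function(model, test_shapes, n_samples = 10000L,
                        n_components = ncol(model$basis), seed = 1L) {
  if (is.list(test_shapes) && inherits(test_shapes[[1L]], "triangle_mesh"))
    test_shapes <- do.call(rbind, lapply(test_shapes, as_shape_vector))
  test_shapes <- as.matrix(test_shapes)
  if (!nrow(test_shapes)) stop("specificity: empty test set")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  nv <- length(model$mean) / 3
  dists <- vapply(seq_len(n_samples), function(s) {
    lam <- model$eigenvalues[seq_len(n_components)]
    a <- stats::rnorm(n_components, 0, sqrt(pmax(lam, 0)))
    x <- model_instance(model, a, as_mesh = FALSE)
    min(vapply(seq_len(nrow(test_shapes)), function(i)
      mean_pervertex_dist(x, test_shapes[i, ]), numeric(1L)))
  }, numeric(1L))
  list(mean = mean(dists), sd = stats::sd(dists), distances = dists)
}

#' Radial crop of a scan around the nose tip
#'
#' The fitting protocol evaluates only the inner facial features: vertices
#' within a fixed Euclidean radius of the annotated nose tip.
#'
#' @param scan a `triangle_mesh`.
#' @param nosetip a 3D point, or a [landmark_set()] (the `nosetip_label`
#'   landmark is used and must be valid).
#' @param radius crop radius (mm).
#' @param nosetip_label label used when `nosetip` is a landmark set.
#' @return logical vertex mask.
#' @export
radial_crop <- function(scan, nosetip, radius, nosetip_label = "nose_tip") {
  if (inherits(nosetip, "landmark_set")) {
    i <- match(nosetip_label, nosetip$labels)
    if (is.na(i) || !nosetip$valid[i])
      stop("radial_crop: nose tip landmark missing or masked")
    nosetip <- nosetip$points[i, ]
  }
  sqrt(rowSums(sweep(scan$points, 2L, nosetip)^2)) <= radius
}

#' Cumulative error distribution curve
#'
#' `y(t)` = fraction of per-vertex errors `<= t`.
#'
#' @param errors non-negative per-vertex errors (mm).
#' @param thresholds strictly increasing thresholds; defaults to 100 steps
#'   spanning the error range.
#' @param model_key label.
#' @return a [curve_result()].
#' @export
ced_curve <- function(errors, thresholds = NULL, model_key = "global") {
  if (any(errors < 0)) stop("ced_curve: negative errors")
  if (is.null(thresholds))
    thresholds <- seq(0, max(errors) + 1e-12, length.out = 100L)
  curve_result(thresholds, vapply(thresholds, function(t) mean(errors <= t),
                                  numeric(1L)),
               metric = "ced_fraction", model_key = model_key)
}

# For each query point, index of the nearest reference point (chunked
# exhaustive search; exact).
nearest_vertices <- function(query, ref, chunk = 512L) {
  query <- as.matrix(query); ref <- as.matrix(ref)
  ref2 <- rowSums(ref^2)
  out <- integer(nrow(query))
  for (start in seq(1L, nrow(query), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(query))
    D2 <- outer(rowSums(query[idx, , drop = FALSE]^2), ref2, "+") -
      2 * query[idx, , drop = FALSE] %*% t(ref)
    out[idx] <- max.col(-D2, "first")
  }
  out
}

#' Fit a morphable model to a raw scan (nearest-vertex protocol)
#'
#' The benchmark fitting recipe: similarity-align the model mean to the scan
#' through shared landmarks; build a pseudo-correspondence by taking, for
#' every model vertex, its nearest scan vertex; project that vector onto the
#' model truncated at `n_components`; then report, for every scan vertex
#' inside a radial crop around the nose tip, the distance to the nearest
#' vertex of the fitted model instance (optionally the distance to the
#' fitted surface instead).
#'
#' @param model a `linear_model` (shape).
#' @param scan raw `triangle_mesh`.
#' @param scan_landmarks [landmark_set()] on the scan.
#' @param model_landmarks [landmark_set()] with `template_indices` into the
#'   model topology.
#' @param n_components modes used in the projection.
#' @param crop_radius radius (mm) of the evaluation crop; `NULL` derives
#'   0.45x the outer-eye-corner distance from the scan landmarks.
#' @param eye_labels labels of the outer eye corners (for the default
#'   radius).
#' @param nosetip_label label of the nose tip.
#' @param point_to_surface measure scan-vertex-to-fitted-surface distance
#'   instead of vertex-to-nearest-vertex.
#' @return list: `fitted` (mesh in scan frame), `errors` (per cropped scan
#'   vertex, mm), `crop_mask`, `coeffs`, `alignment`.
#' @export
fit_to_scan <- function(model, scan, scan_landmarks, model_landmarks,
                        n_components = ncol(model$basis), crop_radius = NULL,
                        eye_labels = c("eye_outer_l", "eye_outer_r"),
                        nosetip_label = "nose_tip",
                        point_to_surface = FALSE) {
  if (is.null(model$trilist))
    stop("fit_to_scan: model carries no topology (trilist)")
  lm <- match_landmarks(model_landmarks, scan_landmarks)
  if (length(lm$k) < 3L)
    stop("fit_to_scan: at least 3 shared valid landmarks required")
  mean_pts <- matrix(model$mean, ncol = 3L, byrow = TRUE)
  to_scan <- procrustes_align(mean_pts[lm$k, , drop = FALSE], lm$L,
                              allow_scale = TRUE)
  to_model <- invert_similarity(to_scan)
  scan_m <- apply_similarity(scan$points, to_model)
  nn <- nearest_vertices(mean_pts, scan_m)
  pseudo <- as.numeric(t(scan_m[nn, , drop = FALSE]))
  pr <- model_project(model, pseudo, n_components = n_components)
  fitted_m <- matrix(pr$reconstruction, ncol = 3L, byrow = TRUE)
  fitted <- triangle_mesh(apply_similarity(fitted_m, to_scan), model$trilist,
                          validate = FALSE)
  if (is.null(crop_radius)) {
    ie <- match(eye_labels, scan_landmarks$labels)
    if (anyNA(ie) || !all(scan_landmarks$valid[ie]))
      stop("fit_to_scan: cannot derive crop radius (eye landmarks missing); give crop_radius")
    crop_radius <- 0.45 * sqrt(sum((scan_landmarks$points[ie[1L], ] -
                                      scan_landmarks$points[ie[2L], ])^2))
  }
  crop <- radial_crop(scan, scan_landmarks, crop_radius,
                      nosetip_label = nosetip_label)
  cropped <- scan$points[crop, , drop = FALSE]
  errors <- if (point_to_surface) {
    closest_point_on_surface(cropped, fitted)$distance
  } else {
    nn2 <- nearest_vertices(cropped, fitted$points)
    sqrt(rowSums((cropped - fitted$points[nn2, , drop = FALSE])^2))
  }
  list(fitted = fitted, errors = errors, crop_mask = crop,
       coeffs = pr$coeffs, alignment = to_scan, crop_radius = crop_radius)
}

#' Default linear SVM classifier plug-in
#'
#' The age-classification demonstration takes any classifier behind a
#' `fit`/`predict` interface; this is the standard choice, a linear support
#' vector machine (requires the `e1071` package).
#'
#' @param cost SVM cost parameter.
#' @return list with `fit(X, y)` and `predict(fit, X)`.
#' @export
linear_svm_classifier <- function(cost = 1) {
  if (!requireNamespace("e1071", quietly = TRUE))
    stop("linear_svm_classifier: package e1071 is required")
  list(
    fit = function(X, y) e1071::svm(as.matrix(X), factor(y),
                                    kernel = "linear", cost = cost),
    predict = function(fit, X) as.character(stats::predict(fit, as.matrix(X))))
}

#' Age classification from shape coefficients
#'
#' Represents every shape by its model projection coefficients, bins
#' subjects into four age classes (half-open bins at the given edges), fits
#' the supplied linear classifier on a stratified training split, and
#' reports per-class and macro precision / recall / F-score on the held-out
#' split.
#'
#' @param model a `linear_model`.
#' @param shapes `k x 3n` matrix or list of corresponded meshes.
#' @param records `demographic_records` aligned with `shapes`.
#' @param classifier a `fit`/`predict` plug-in
#'   (default [linear_svm_classifier()]).
#' @param train_frac stratified training fraction.
#' @param seed RNG seed for the split.
#' @param age_edges age class edges (years).
#' @param n_components number of coefficient features.
#' @return list with `per_class` (data frame), `macro`
#'   (precision/recall/f1), `confusion`, and the split indices.
#' @export
age_class_demo <- function(model, shapes, records,
                           classifier = linear_svm_classifier(),
                           train_frac = 0.7, seed = 1L,
                           age_edges = c(7, 18, 50),
                           n_components = ncol(model$basis)) {
  if (is.list(shapes) && inherits(shapes[[1L]], "triangle_mesh"))
    shapes <- do.call(rbind, lapply(shapes, as_shape_vector))
  shapes <- as.matrix(shapes)
  k <- nrow(shapes)
  if (nrow(records) != k)
    stop("age_class_demo: one demographic record per shape required")
  X <- t(vapply(seq_len(k), function(i)
    model_project(model, shapes[i, ], n_components = n_components)$coeffs,
    numeric(n_components)))
  cls_labels <- c(paste0("under_", age_edges[1L]),
                  paste0(age_edges[1L], "_to_", age_edges[2L]),
                  paste0(age_edges[2L], "_to_", age_edges[3L]),
                  paste0("over_", age_edges[3L]))
  y <- cut(records$age, breaks = c(-Inf, age_edges, Inf), labels = cls_labels,
           right = FALSE)
  y <- as.character(y)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  train <- logical(k)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_tr <- max(1L, round(train_frac * length(idx)))
    train[sample(idx, n_tr)] <- TRUE
  }
  missing_train <- setdiff(cls_labels, unique(y[train]))
  if (length(missing_train))
    stop("age_class_demo: class(es) absent from training split: ",
         paste(missing_train, collapse = ", "))
  if (length(unique(y[!train])) < 2L)
    stop("age_class_demo: test split contains a single class (",
         paste(unique(y[!train]), collapse = ""), ")")
  fit <- classifier$fit(X[train, , drop = FALSE], y[train])
  pred <- classifier$predict(fit, X[!train, , drop = FALSE])
  truth <- y[!train]
  per_class <- do.call(rbind, lapply(cls_labels, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    data.frame(class = cl, support = sum(truth == cl),
               precision = p, recall = r, f1 = f)
  }))
  present <- per_class$support > 0
  macro <- c(precision = mean(per_class$precision[present]),
             recall = mean(per_class$recall[present]),
             f1 = mean(per_class$f1[present]))
  list(per_class = per_class, macro = macro,
       confusion = table(truth = truth, predicted = pred),
       train_index = which(train), test_index = which(!train),
       accuracy = mean(pred == truth))
}
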