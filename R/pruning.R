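# Automatic detection of failed registrations. Under the probabilistic
# reading of the PCA model, each shape coefficient alpha_i is independent
# N(0, lambda_i), so the squared Mahalanobis distance
# F(alpha) = sum_i alpha_i^2 / lambda_i is chi-square with d degrees of
# freedom. Registration failures behave as gross outliers of that
# distribution and are excluded before the final model build.

#' Squared Mahalanobis plausibility score of a shape vector
#'
#' `F(alpha) = sum_i alpha_i^2 / lambda_i`, the squared Mahalanobis distance
#' of the shape from the model mean in coefficient space. Components whose
#' eigenvalue falls below `floor_frac * lambda_1` are excluded from both the
#' sum and the degrees of freedom.
#'
#' @param model a `linear_model`.
#' @param coeffs coefficient vector of length `<=` number of modes.
#' @param floor_frac eigenvalue floor as a fraction of the leading eigenvalue.
#' @return scalar `F`; attribute `"df"` gives the effective degrees of freedom.
#' @export
mahalanobis_sq <- function(model, coeffs, floor_frac = 1e-12) {
  lam <- model$eigenvalues[seq_along(coeffs)]
  keep <- lam > floor_frac * model$eigenvalues[1L]
  if (!any(keep))
    stop("mahalanobis_sq: all eigenvalues below the floor")
  f <- sum(coeffs[keep]^2 / lam[keep])
  attr(f, "df") <- sum(keep)
  f
}

#' Chi-square plausibility threshold
#'
#' The unique `theta` with `P(chi2_d <= theta) = p_f`: shapes scored above it
#' are implausible under the model's Gaussian at confidence `p_f`.
#'
#' @param d positive integer degrees of freedom.
#' @param p_f probability level in (0, 1).
#' @return scalar threshold `theta_f`.
#' @export
chi2_threshold <- function(d, p_f) {
  if (!is.numeric(d) || d < 1 || d != round(d))
    stop("chi2_threshold: d must be a positive integer")
  if (!is.numeric(p_f) || p_f <= 0 || p_f >= 1)
    stop("chi2_threshold: p_f must lie strictly in (0, 1)")
  stats::qchisq(p_f, df = d)
}

#' Prune implausible registrations and rebuild the model
#'
#' Two-pass model construction: (1) an initial global PCA over all
#' corresponded shapes; (2) every shape is projected onto it and scored with
#' [mahalanobis_sq()]; shapes scoring above [chi2_threshold()] at level
#' `p_f` are flagged as registration failures; (3) the final model(s) are
#' rebuilt from the surviving shapes only. A single pass — no re-iteration.
#'
#' Shapes are expected to be Procrustes-aligned (e.g. via
#' [generalized_procrustes()]) before scoring.
#'
#' @param shapes `k x 3n` matrix, or list of corresponded meshes, `k >= 3`.
#' @param p_f plausibility level (default 0.99).
#' @param subject_ids optional identifiers (default row numbers).
#' @param variance_to_retain,n_components truncation rule, applied to both
#'   the initial and the final build.
#' @param trilist,kind passed to [build_pca()].
#' @return list with `model` (final `linear_model`) and `report` (a
#'   `pruning_report`: per-subject scores, threshold, flagged ids, degrees of
#'   freedom).
#' @export
prune_and_rebuild <- function(shapes, p_f = 0.99, subject_ids = NULL,
                              variance_to_retain = 0.995, n_components = NULL,
                              trilist = NULL, kind = "shape") {
  if (is.list(shapes) && inherits(shapes[[1L]], "triangle_mesh")) {
    trilist <- shapes[[1L]]$trilist
    shapes <- do.call(rbind, lapply(shapes, as_shape_vector))
  }
  shapes <- as.matrix(shapes)
  k <- nrow(shapes)
  if (k < 3L) stop("prune_and_rebuild: at least 3 shapes required")
  if (is.null(subject_ids)) subject_ids <- as.character(seq_len(k))
  initial <- build_pca(shapes, variance_to_retain = variance_to_retain,
                       n_components = n_components, trilist = trilist,
                       kind = kind)
  scores <- numeric(k)
  df <- NA_integer_
  for (i in seq_len(k)) {
    f <- mahalanobis_sq(initial, model_project(initial, shapes[i, ])$coeffs)
    scores[i] <- f
    df <- attr(f, "df")
  }
  theta <- chi2_threshold(df, p_f)
  flagged <- scores > theta
  if (k - sum(flagged) < 2L)
    stop("prune_and_rebuild: pruning would leave fewer than 2 shapes")
  final <- build_pca(shapes[!flagged, , drop = FALSE],
                     variance_to_retain = variance_to_retain,
                     n_components = n_components, trilist = trilist,
                     kind = kind)
  report <- structure(list(subject_ids = subject_ids, scores = scores,
                           threshold = theta, p_f = p_f, df = df,
                           flagged = subject_ids[flagged],
                           n_total = k, n_flagged = sum(flagged)),
                      class = "pruning_report")
  list(model = final, initial_model = initial, report = report)
}

#' @export
print.pruning_report <- function(x, ...) {
  cat(sprintf(
    "pruning_report: %d / %d subjects flagged (F > %.3f at p_f = %g, df = %d)\n",
    x$n_flagged, x$n_total, x$threshold, x$p_f, x$df))
  invisible(x)
}

#' Write a pruning report (CSV of scores + JSON summary)
#'
#' @param report a `pruning_report`.
#' @param csv_path per-subject CSV (`subject_id`, `F`, `flagged`).
#' @param json_path summary JSON (`theta_f`, `p_f`, `df`, counts).
#' @export
write_pruning_report <- function(report, csv_path, json_path = NULL) {
  utils::write.csv(
    data.frame(subject_id = report$subject_ids, F = report$scores,
               flagged = report$subject_ids %in% report$flagged),
    csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(theta_f = report$threshold, p_f = report$p_f, df = report$df,
           n_total = report$n_total, n_flagged = report$n_flagged,
           flagged = report$flagged),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
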