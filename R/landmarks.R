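#' Construct a named landmark set
#'
#' Sparse named 3D points attached either to a raw mesh (free points) or to a
#' template (vertex indices). Invalid landmarks (e.g. occluded in every
#' rendered view) carry `valid = FALSE` and may have undefined coordinates.
#'
#' @param labels character vector of unique landmark names (length `L`).
#' @param points `L x 3` numeric matrix (mm); rows where `valid` is `FALSE`
#'   may be non-finite.
#' @param template_indices optional integer vector of length `L`: the vertex
#'   index of each landmark on the template mesh.
#' @param valid logical vector of length `L`; defaults to all `TRUE`.
#' @param confidence optional numeric vector in `[0, 1]`, e.g. from a 2D
#'   detector.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(labels, points, template_indices = NULL,
                         valid = NULL, confidence = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("landmark labels must be unique")
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L || nrow(points) != length(labels))
    stop("landmark points must be an L x 3 matrix matching labels")
  if (is.null(valid)) valid <- rep(TRUE, length(labels))
  valid <- as.logical(valid)
  if (length(valid) != length(labels))
    stop("valid mask length must match labels")
  if (any(valid & !apply(is.finite(points), 1L, all)))
    stop("landmark marked valid has non-finite coordinates")
  if (!is.null(template_indices)) {
    template_indices <- as.integer(template_indices)
    if (length(template_indices) != length(labels))
      stop("template_indices length must match labels")
  }
  if (!is.null(confidence)) {
    confidence <- as.numeric(confidence)
    if (length(confidence) != length(labels) ||
        any(confidence < 0 | confidence > 1, na.rm = TRUE))
      stop("confidence must be length L with values in [0, 1]")
  }
  structure(list(labels = labels, points = points,
                 template_indices = template_indices, valid = valid,
                 confidence = confidence),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark_set: %d landmarks (%d valid)%s\n",
              length(x$labels), sum(x$valid),
              if (!is.null(x$template_indices)) ", template-attached" else ""))
  invisible(x)
}

#' Read / write landmark sets as JSON
#'
#' File schema:
#' `{"version": 1, "labels": [...], "points": [[x,y,z], ...], "valid": [...]}`.
#' Optional keys `template_indices` (1-based) and `confidence` round-trip when
#' present. Masked (invalid) points may be stored as `null` coordinates.
#'
#' @param path file path.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file does not exist: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (key in c("labels", "points", "valid"))
    if (is.null(obj[[key]]))
      stop("landmark schema error: missing key '", key, "' in ", path)
  pts <- obj$points
  if (is.list(pts))
    pts <- t(vapply(pts, function(r) {
      r <- as.numeric(r)
      length(r) <- 3L
      r
    }, numeric(3L)))
  pts <- as.matrix(pts)
  pts[is.na(pts)] <- NaN
  landmark_set(obj$labels, pts,
               template_indices = obj$template_indices,
               valid = obj$valid, confidence = obj$confidence)
}

#' @rdname read_landmarks
#' @param lms a [landmark_set()].
#' @export
write_landmarks <- function(lms, path) {
  pts <- lms$points
  pts[!is.finite(pts)] <- NA  # -> JSON null
  obj <- list(version = 1L, labels = lms$labels, points = pts,
              valid = lms$valid)
  if (!is.null(lms$template_indices))
    obj$template_indices <- lms$template_indices
  if (!is.null(lms$confidence)) obj$confidence <- lms$confidence
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Demographic record(s) for model training subjects
#'
#' Validates a data frame of per-subject metadata: `subject_id`, `age`
#' (years, non-negative), `gender` and `ethnicity` (categories from a
#' declared vocabulary).
#'
#' @param subject_id character vector.
#' @param age numeric vector, years, `>= 0`.
#' @param gender character vector.
#' @param ethnicity character vector.
#' @param vocabulary list with elements `gender` and `ethnicity` giving the
#'   allowed categories; `NULL` skips the vocabulary check.
#' @return a `data.frame` of class `demographic_records`.
#' @export
demographic_records <- function(subject_id, age, gender, ethnicity,
                                vocabulary = NULL) {
  age <- as.numeric(age)
  if (any(!is.finite(age)) || any(age < 0))
    stop("demographics: age must be finite and >= 0")
  gender <- as.character(gender)
  ethnicity <- as.character(ethnicity)
  if (!is.null(vocabulary)) {
    if (!is.null(vocabulary$gender) && !all(gender %in% vocabulary$gender))
      stop("demographics: gender value outside declared vocabulary: ",
           paste(setdiff(gender, vocabulary$gender), collapse = ", "))
    if (!is.null(vocabulary$ethnicity) &&
        !all(ethnicity %in% vocabulary$ethnicity))
      stop("demographics: ethnicity value outside declared vocabulary: ",
           paste(setdiff(ethnicity, vocabulary$ethnicity), collapse = ", "))
  }
  out <- data.frame(subject_id = as.character(subject_id), age = age,
                    gender = gender, ethnicity = ethnicity,
                    stringsAsFactors = FALSE)
  class(out) <- c("demographic_records", "data.frame")
  out
}

#' Read a demographics CSV (subject_id, age, gender, ethnicity)
#' @param path CSV file path.
#' @param vocabulary see [demographic_records()].
#' @export
read_demographics <- function(path, vocabulary = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "gender", "ethnicity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("demographics CSV missing column(s): ", paste(miss, collapse = ", "))
  demographic_records(df$subject_id, df$age, df$gender, df$ethnicity,
                      vocabulary = vocabulary)
}
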