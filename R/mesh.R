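#' Construct a triangle mesh
#'
#' The canonical surface container used throughout the package: an `n x 3`
#' matrix of vertex coordinates (millimetres), an `m x 3` integer matrix of
#' vertex index triplets (1-based, the R convention), and optionally an
#' `n x 3` matrix of per-vertex RGB colors with each channel in `[0, 1]`.
#'
#' @param points numeric `n x 3` matrix of vertex coordinates (mm).
#' @param trilist integer `m x 3` matrix of 1-based vertex indices.
#' @param colors optional numeric `n x 3` matrix, channels in `[0, 1]`.
#' @param validate if `TRUE` (default), check all invariants.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(points, trilist, colors = NULL, validate = TRUE) {
  points <- unname(as.matrix(points))
  storage.mode(points) <- "double"
  trilist <- unname(as.matrix(trilist))
  storage.mode(trilist) <- "integer"
  if (!is.null(colors)) {
    colors <- unname(as.matrix(colors))
    storage.mode(colors) <- "double"
  }
  mesh <- structure(list(points = points, trilist = trilist, colors = colors),
                    class = "triangle_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' Validate the invariants of a triangle mesh
#'
#' Checks coordinate finiteness, index bounds, degenerate index triplets and
#' color shape/range. Called by [triangle_mesh()]; exported so that meshes
#' assembled field-by-field can be re-checked.
#'
#' @param mesh a `triangle_mesh`.
#' @return `mesh`, invisibly; errors describe the first violated invariant.
#' @export
validate_mesh <- function(mesh) {
  p <- mesh$points; t <- mesh$trilist
  if (!is.matrix(p) || ncol(p) != 3L)
    stop("mesh validation: points must be an n x 3 matrix")
  if (!all(is.finite(p)))
    stop("mesh validation: non-finite vertex coordinate at row ",
         which(!apply(is.finite(p), 1L, all))[1L])
  if (!is.matrix(t) || ncol(t) != 3L)
    stop("mesh validation: trilist must be an m x 3 matrix")
  n <- nrow(p)
  if (nrow(t) > 0L) {
    if (anyNA(t) || min(t) < 1L || max(t) > n)
      stop("mesh validation: trilist index out of range [1, ", n, "] at row ",
           which(apply(t, 1L, function(r) anyNA(r) || any(r < 1L | r > n)))[1L])
    degen <- t[, 1L] == t[, 2L] | t[, 1L] == t[, 3L] | t[, 2L] == t[, 3L]
    if (any(degen))
      stop("mesh validation: triangle repeats a vertex index at row ",
           which(degen)[1L])
  }
  if (!is.null(mesh$colors)) {
    cl <- mesh$colors
    if (!is.matrix(cl) || ncol(cl) != 3L || nrow(cl) != n)
      stop("mesh validation: colors must be an n x 3 matrix matching points")
    if (anyNA(cl) || min(cl) < 0 || max(cl) > 1)
      stop("mesh validation: color channel outside [0, 1]")
  }
  invisible(mesh)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d triangles%s\n",
              nrow(x$points), nrow(x$trilist),
              if (!is.null(x$colors)) ", per-vertex color" else ""))
  invisible(x)
}

#' Unique undirected edges of a mesh
#'
#' @param mesh a `triangle_mesh`.
#' @return integer `E x 2` matrix, each row `i < j`, sorted.
#' @export
mesh_edges <- function(mesh) {
  t <- mesh$trilist
  e <- rbind(t[, c(1L, 2L)], t[, c(2L, 3L)], t[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e <- unique(e)
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}

# Edge occurrence counts; boundary edges appear in exactly one triangle.
edge_counts <- function(mesh) {
  t <- mesh$trilist
  e <- rbind(t[, c(1L, 2L)], t[, c(2L, 3L)], t[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  table(key)
}

#' Boundary vertices of a mesh
#'
#' A vertex is a boundary vertex if it belongs to an edge used by exactly one
#' triangle (open surface rim, hole rims).
#'
#' @param mesh a `triangle_mesh`.
#' @return logical vector of length `n`.
#' @export
boundary_vertices <- function(mesh) {
  n <- nrow(mesh$points)
  out <- logical(n)
  cnt <- edge_counts(mesh)
  b <- names(cnt)[cnt == 1L]
  if (length(b)) {
    idx <- as.integer(unlist(strsplit(b, " ", fixed = TRUE)))
    out[idx] <- TRUE
  }
  out
}

#' Per-triangle unit normals
#'
#' @param mesh a `triangle_mesh`.
#' @return `m x 3` matrix of unit normals (right-hand rule on vertex order).
#' @export
triangle_normals <- function(mesh) {
  p <- mesh$points; t <- mesh$trilist
  a <- p[t[, 1L], , drop = FALSE]
  e1 <- p[t[, 2L], , drop = FALSE] - a
  e2 <- p[t[, 3L], , drop = FALSE] - a
  nrm <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
               e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
               e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm / len
}

#' Per-vertex unit normals (area-weighted average of incident triangles)
#'
#' @param mesh a `triangle_mesh`.
#' @return `n x 3` matrix of unit normals; zero rows for isolated vertices.
#' @export
vertex_normals <- function(mesh) {
  p <- mesh$points; t <- mesh$trilist
  a <- p[t[, 1L], , drop = FALSE]
  e1 <- p[t[, 2L], , drop = FALSE] - a
  e2 <- p[t[, 3L], , drop = FALSE] - a
  # cross product magnitude = 2 * area, so this is area weighting for free
  fn <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  vn <- matrix(0, nrow(p), 3L)
  for (k in 1:3) {
    idx <- t[, k]
    vn[, 1L] <- vn[, 1L] + unname(tapply_sum(fn[, 1L], idx, nrow(p)))
    vn[, 2L] <- vn[, 2L] + unname(tapply_sum(fn[, 2L], idx, nrow(p)))
    vn[, 3L] <- vn[, 3L] + unname(tapply_sum(fn[, 3L], idx, nrow(p)))
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}

tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

#' Mean edge length of a mesh (mm)
#' @param mesh a `triangle_mesh`.
#' @return scalar mean Euclidean edge length.
#' @export
mean_edge_length <- function(mesh) {
  e <- mesh_edges(mesh)
  d <- mesh$points[e[, 1L], , drop = FALSE] - mesh$points[e[, 2L], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' Flatten mesh vertices to a length-3n shape vector (and back)
#'
#' The modelling code works on shape vectors `[x1 y1 z1 x2 y2 z2 ...]`.
#'
#' @param mesh a `triangle_mesh`.
#' @return numeric vector of length `3n`.
#' @export
as_shape_vector <- function(mesh) as.numeric(t(mesh$points))

#' @rdname as_shape_vector
#' @param x length-3n numeric vector.
#' @param trilist shared topology for the rebuilt mesh.
#' @param colors optional colors for the rebuilt mesh.
#' @export
shape_vector_to_mesh <- function(x, trilist, colors = NULL) {
  triangle_mesh(matrix(x, ncol = 3L, byrow = TRUE), trilist, colors = colors)
}

# Connected components of the vertex graph (for singular-system diagnostics).
vertex_components <- function(mesh) {
  n <- nrow(mesh$points)
  e <- mesh_edges(mesh)
  comp <- integer(n)
  adj <- vector("list", n)
  for (r in seq_len(nrow(e))) {
    adj[[e[r, 1L]]] <- c(adj[[e[r, 1L]]], e[r, 2L])
    adj[[e[r, 2L]]] <- c(adj[[e[r, 2L]]], e[r, 1L])
  }
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

#' Centroid size of a point configuration
#' @param points `n x 3` matrix.
#' @return square root of the sum of squared deviations from the centroid.
#' @export
centroid_size <- function(points) {
  c0 <- colMeans(points)
  sqrt(sum(sweep(points, 2L, c0)^2))
}

# Apply a similarity transform (s, R, t) to an n x 3 point matrix.
apply_similarity <- function(points, trafo) {
  sweep(points %*% t(trafo$R) * trafo$s, 2L, trafo$t, "+")
}
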