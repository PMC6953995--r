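# Exact point-to-triangle-mesh distance queries.
#
# The data term of the registration energy needs, for every deformed template
# vertex, the exact nearest point on the target surface over all triangles
# (vertex / edge / interior cases). The core is a fully vectorized version of
# the standard Voronoi-region closest-point-on-triangle computation, run over
# (query, triangle) pairs; a centroid-ball prefilter discards triangles that
# provably cannot contain a query's nearest point before the exact test.

# Vectorized closest point on triangles (a,b,c) from points p; all k x 3.
# Returns the closest point, barycentric coordinates (u,v,w), and squared
# distance for each row.
point_triangle_closest <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- p - b
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- p - c
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4

  k <- nrow(p)
  u <- numeric(k); v <- numeric(k); w <- numeric(k)
  done <- logical(k)

  take <- function(cond) {
    sel <- cond & !done
    done[sel] <<- TRUE
    sel
  }

  sel <- take(d1 <= 0 & d2 <= 0)               # vertex a
  u[sel] <- 1
  sel <- take(d3 >= 0 & d4 <= d3)              # vertex b
  v[sel] <- 1
  sel <- take(vc <= 0 & d1 >= 0 & d3 <= 0)     # edge ab
  tpar <- d1[sel] / (d1[sel] - d3[sel])
  v[sel] <- tpar; u[sel] <- 1 - tpar
  sel <- take(d6 >= 0 & d5 <= d6)              # vertex c
  w[sel] <- 1
  sel <- take(vb <= 0 & d2 >= 0 & d6 <= 0)     # edge ac
  tpar <- d2[sel] / (d2[sel] - d6[sel])
  w[sel] <- tpar; u[sel] <- 1 - tpar
  sel <- take(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0)  # edge bc
  tpar <- (d4[sel] - d3[sel]) / ((d4[sel] - d3[sel]) + (d5[sel] - d6[sel]))
  w[sel] <- tpar; v[sel] <- 1 - tpar
  sel <- !done                                  # interior
  denom <- 1 / (va[sel] + vb[sel] + vc[sel])
  v[sel] <- vb[sel] * denom
  w[sel] <- vc[sel] * denom
  u[sel] <- 1 - v[sel] - w[sel]

  pt <- a * u + b * v + c * w
  list(point = pt, bary = cbind(u, v, w), dist2 = rowSums((p - pt)^2))
}

#' Exact closest point on a triangulated surface
#'
#' For each query point, returns the exact nearest point over all triangles of
#' the target mesh (handling vertex, edge and interior cases), the Euclidean
#' distance, the triangle index, and the barycentric coordinates of the foot
#' point within that triangle.
#'
#' @param query a length-3 vector or `q x 3` matrix of query points (mm).
#' @param target a non-empty `triangle_mesh`.
#' @param chunk number of queries processed per block (memory control).
#' @return list with elements `point` (`q x 3`), `distance` (length `q`),
#'   `triangle` (length `q`, 1-based), `bary` (`q x 3`).
#' @export
closest_point_on_surface <- function(query, target, chunk = 256L) {
  if (is.null(dim(query))) query <- matrix(query, ncol = 3L, byrow = TRUE)
  query <- as.matrix(query)
  m <- nrow(target$trilist)
  if (m == 0L) stop("closest_point_on_surface: target mesh has no triangles")
  p <- target$points; t <- target$trilist
  A <- p[t[, 1L], , drop = FALSE]
  B <- p[t[, 2L], , drop = FALSE]
  C <- p[t[, 3L], , drop = FALSE]
  cent <- (A + B + C) / 3
  rad <- sqrt(pmax(rowSums((A - cent)^2),
                   rowSums((B - cent)^2),
                   rowSums((C - cent)^2)))
  nq <- nrow(query)
  out_pt <- matrix(0, nq, 3L)
  out_d <- numeric(nq)
  out_tri <- integer(nq)
  out_bary <- matrix(0, nq, 3L)
  cent2 <- rowSums(cent^2)
  for (start in seq(1L, nq, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nq)
    Q <- query[idx, , drop = FALSE]
    # centroid distances: |q|^2 - 2 q.c + |c|^2
    D2 <- outer(rowSums(Q^2), cent2, "+") - 2 * Q %*% t(cent)
    D <- sqrt(pmax(D2, 0))
    lower <- sweep(D, 2L, rad, "-")              # lower bound on true distance
    ub <- apply(sweep(D, 2L, rad, "+"), 1L, min) # upper bound via best centroid
    keep <- which(lower <= ub, arr.ind = TRUE)   # candidate (query, tri) pairs
    qi <- keep[, 1L]; ti <- keep[, 2L]
    res <- point_triangle_closest(Q[qi, , drop = FALSE],
                                  A[ti, , drop = FALSE],
                                  B[ti, , drop = FALSE],
                                  C[ti, , drop = FALSE])
    o <- order(qi, res$dist2)
    first <- o[!duplicated(qi[o])]
    sel_q <- qi[first]
    out_pt[idx[sel_q], ] <- res$point[first, , drop = FALSE]
    out_d[idx[sel_q]] <- sqrt(res$dist2[first])
    out_tri[idx[sel_q]] <- ti[first]
    out_bary[idx[sel_q], ] <- res$bary[first, , drop = FALSE]
  }
  list(point = out_pt, distance = out_d, triangle = out_tri, bary = out_bary)
}
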