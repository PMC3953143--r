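#' Euclidean distance between two 3D points
#'
#' @param p,q Numeric length-3 vectors (Angstrom).
#' @return Distance in the same units as the inputs.
#' @examples
#' euclidean(c(0, 0, 0), c(3, 4, 0)) # 5
#' @export
euclidean <- function(p, q) {
  stopifnot(length(p) == 3L, length(q) == 3L, all(is.finite(p)), all(is.finite(q)))
  sqrt(sum((p - q)^2))
}

#' Perpendicular distance from a point to an infinite line
#'
#' Distance from `p` to the infinite line through `a` and `b`. A degenerate
#' line (`a == b`) falls back to the point-to-point distance; this keeps the
#' Douglas-Peucker test line well defined on closed or folded paths.
#'
#' @param p Numeric length-3 point.
#' @param a,b Numeric length-3 points defining the line.
#' @return Distance (Angstrom).
#' @export
point_line_distance <- function(p, a, b) {
  d <- b - a
  n2 <- sum(d^2)
  if (n2 == 0) return(euclidean(p, a))
  v <- p - a
  cr <- c(v[2] * d[3] - v[3] * d[2],
          v[3] * d[1] - v[1] * d[3],
          v[1] * d[2] - v[2] * d[1])
  sqrt(sum(cr^2) / n2)
}

#' Distance from a point to a finite segment
#'
#' Minimum over t in \[0, 1\] of the distance from `p` to `a + t (b - a)`:
#' the perpendicular distance where the foot of the perpendicular falls inside
#' the segment, otherwise the distance to the nearest segment endpoint. Used
#' for the helix-region mask, where the helix central axis is a finite segment.
#'
#' @inheritParams point_line_distance
#' @return Distance (Angstrom).
#' @export
point_segment_distance <- function(p, a, b) {
  d <- b - a
  n2 <- sum(d^2)
  if (n2 == 0) return(euclidean(p, a))
  t <- sum((p - a) * d) / n2
  t <- min(1, max(0, t))
  euclidean(p, a + t * d)
}

# Vectorised segment distance: rows of `pts` (n x 3) against segment a-b.
points_segment_distance <- function(pts, a, b) {
  d <- b - a
  n2 <- sum(d^2)
  if (n2 == 0) {
    return(sqrt(rowSums(sweep(pts, 2, a)^2)))
  }
  v <- sweep(pts, 2, a)
  t <- pmin(1, pmax(0, as.vector(v %*% d) / n2))
  foot <- outer(t, d)
  sqrt(rowSums((v - foot)^2))
}

# Vectorised point-to-infinite-line distance for the Douglas-Peucker inner loop.
points_line_distance <- function(pts, a, b) {
  d <- b - a
  n2 <- sum(d^2)
  if (n2 == 0) {
    return(sqrt(rowSums(sweep(pts, 2, a)^2)))
  }
  v <- sweep(pts, 2, a)
  t <- as.vector(v %*% d) / n2
  foot <- outer(t, d)
  sqrt(rowSums((v - foot)^2))
}

#' Length of a polyline
#'
#' Sum of the Euclidean lengths of consecutive segments; zero-length segments
#' contribute zero and a single-vertex polyline has length zero.
#'
#' @param vertices Numeric matrix with one vertex per row (columns x, y, z).
#' @return Total length (Angstrom).
#' @examples
#' polyline_length(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))) # 2
#' @export
polyline_length <- function(vertices) {
  vertices <- as_point_matrix(vertices)
  n <- nrow(vertices)
  if (n < 2L) return(0)
  steps <- vertices[-1L, , drop = FALSE] - vertices[-n, , drop = FALSE]
  sum(sqrt(rowSums(steps^2)))
}

# Coerce a point, list of points, or n x 3 matrix to an n x 3 numeric matrix.
as_point_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3L)
    storage.mode(x) <- "double"
    return(x)
  }
  if (is.numeric(x) && length(x) == 3L) {
    return(matrix(x, nrow = 1L))
  }
  if (is.list(x)) {
    return(do.call(rbind, lapply(x, function(p) as.numeric(p))))
  }
  stop("cannot interpret input as 3D points")
}

# Lexicographic (x, then y, then z) ordering permutation of point rows.
lex_order <- function(pts) {
  order(pts[, 1L], pts[, 2L], pts[, 3L])
}
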