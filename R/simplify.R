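# Per-vertex retention thresholds for Douglas-Peucker simplification.
#
# The recursion tree of the algorithm depends only on geometry: each segment
# is split at its most distant interior vertex (earliest index on ties)
# regardless of epsilon. A vertex survives at tolerance eps iff its own split
# distance and those of all enclosing splits exceed eps, so each interior
# vertex gets the threshold min(own distance, parent threshold) and a single
# pass answers every epsilon. Endpoints get +Inf.
dp_significance <- function(vertices) {
  vertices <- as_point_matrix(vertices)
  n <- nrow(vertices)
  if (n < 2L) stop("Douglas-Peucker needs at least 2 vertices")
  sig <- rep(Inf, n)
  stack <- list(list(i = 1L, j = n, cap = Inf))
  while (length(stack) > 0L) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- fr$i; j <- fr$j
    if (j - i < 2L) next
    interior <- vertices[(i + 1L):(j - 1L), , drop = FALSE]
    d <- points_line_distance(interior, vertices[i, ], vertices[j, ])
    m <- which.max(d)            # earliest index on ties
    s <- min(d[m], fr$cap)
    k <- i + m
    sig[k] <- s
    stack[[length(stack) + 1L]] <- list(i = i, j = k, cap = s)
    stack[[length(stack) + 1L]] <- list(i = k, j = j, cap = s)
  }
  sig
}

#' Douglas-Peucker simplification of a 3D polyline
#'
#' Recursively removes vertices lying within a band of half-width `epsilon`
#' of the test line through the current segment's endpoints: if the most
#' distant interior vertex deviates by more than `epsilon` the segment is
#' split there and both halves are simplified; otherwise only the endpoints
#' are kept. Distances are to the infinite test line; a degenerate test line
#' (coincident endpoints) falls back to point distance. At `epsilon = 0` only
#' exactly collinear vertices are removed, which leaves the measured length
#' unchanged.
#'
#' @param vertices Polyline as an n x 3 matrix (n >= 2).
#' @param epsilon Band half-width in Angstrom (>= 0).
#' @return The simplified polyline: a subsequence of the input rows including
#'   both endpoints.
#' @export
douglas_peucker <- function(vertices, epsilon) {
  stopifnot(epsilon >= 0)
  vertices <- as_point_matrix(vertices)
  sig <- dp_significance(vertices)
  vertices[sig > epsilon, , drop = FALSE]
}

#' Measure the simplified length of a loop path
#'
#' Length of the Douglas-Peucker-simplified path, including the two
#' endpoint-attachment segments: the loop is measured along the skeleton
#' between (and including) the endpoints of the two surrounding helices.
#'
#' @param path A `loop_path` from [find_loop_paths()], or a vertex matrix.
#' @param epsilon Simplification tolerance in Angstrom.
#' @return Measured length in Angstrom.
#' @export
measure_loop <- function(path, epsilon) {
  v <- if (inherits(path, "loop_path")) {
    if (!isTRUE(path$feasible)) stop("cannot measure an infeasible loop path")
    path$vertices
  } else {
    as_point_matrix(path)
  }
  polyline_length(douglas_peucker(v, epsilon))
}

#' Expected loop length from its residue count
#'
#' `3.8 * (n + 1)` Angstrom for a loop of `n` amino acids, 3.8 Angstrom being
#' the mean distance between sequence-adjacent residues. This sequence-derived
#' expectation is what the skeleton measurement is compared against.
#'
#' @param n Number of residues on the loop (non-negative integer, vectorised).
#' @return Expected length in Angstrom.
#' @examples
#' expected_length(3) # 15.2
#' @export
expected_length <- function(n) {
  if (any(n < 0) || any(n != round(n))) stop("n must be a non-negative integer")
  3.8 * (n + 1)
}

#' Absolute and relative error of a measured loop length
#'
#' @param measured,expected Lengths in Angstrom (`expected > 0`).
#' @return List with `diff` (|measured - expected|, Angstrom) and `rel_err`
#'   (percent of the expected length).
#' @export
error_metrics <- function(measured, expected) {
  stopifnot(all(expected > 0))
  d <- abs(measured - expected)
  list(diff = d, rel_err = 100 * d / expected)
}

#' Sweep the Douglas-Peucker tolerance and record the measured lengths
#'
#' The measured length as a function of epsilon is a non-increasing step
#' function (retained vertex sets are nested in epsilon). When an expected
#' length is supplied, `best_epsilon` is the smallest sampled epsilon whose
#' measurement is closest to it — an evaluation device requiring the expected
#' length, not a blind selector.
#'
#' @param path A feasible `loop_path` or vertex matrix.
#' @param eps_min,eps_max,step Sweep grid (defaults 0 to 6 by 0.05 Angstrom).
#' @param expected Optional expected length in Angstrom.
#' @return List of class `epsilon_sweep` with `epsilon`, `measured`,
#'   `best_epsilon`, `best_measured`, `expected`.
#' @export
epsilon_sweep <- function(path, eps_min = 0, eps_max = 6, step = 0.05,
                          expected = NULL) {
  stopifnot(eps_min <= eps_max, step > 0)
  v <- if (inherits(path, "loop_path")) {
    if (!isTRUE(path$feasible)) stop("cannot sweep an infeasible loop path")
    path$vertices
  } else {
    as_point_matrix(path)
  }
  eps <- seq(eps_min, eps_max, by = step)
  sig <- dp_significance(v)
  measured <- vapply(eps, function(e) polyline_length(v[sig > e, , drop = FALSE]),
                     numeric(1L))
  out <- list(epsilon = eps, measured = measured,
              best_epsilon = NA_real_, best_measured = NA_real_,
              expected = if (is.null(expected)) NA_real_ else expected)
  if (!is.null(expected)) {
    best <- which.min(abs(measured - expected))  # first (smallest eps) on ties
    out$best_epsilon <- eps[best]
    out$best_measured <- measured[best]
  }
  structure(out, class = "epsilon_sweep")
}

#' @export
print.epsilon_sweep <- function(x, ...) {
  cat(sprintf("epsilon sweep: %d samples in [%g, %g], measured %.3f -- %.3f A\n",
              length(x$epsilon), min(x$epsilon), max(x$epsilon),
              max(x$measured), min(x$measured)))
  if (!is.na(x$best_epsilon)) {
    cat(sprintf("  best epsilon %.2f A -> %.4f A (expected %.4f A)\n",
                x$best_epsilon, x$best_measured, x$expected))
  }
  invisible(x)
}

#' @export
plot.epsilon_sweep <- function(x, ...) {
  graphics::plot(x$epsilon, x$measured, type = "s",
                 xlab = expression(epsilon ~ "(Å)"),
                 ylab = "measured length (Å)", ...)
  if (!is.na(x$expected)) {
    graphics::abline(h = x$expected, lty = 2L)
    graphics::points(x$best_epsilon, x$best_measured, pch = 19L)
  }
  invisible(x)
}
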