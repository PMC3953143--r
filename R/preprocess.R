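#' Remove skeleton voxels inside the helix regions
#'
#' Helix detection and skeletonization are independent, so skeleton voxels
#' that trace the helices themselves must be removed before the loop skeleton
#' can be isolated. A point is removed when its distance to any helix central
#' axis (a finite segment) is within `radius`; an alpha-helix is about
#' 2.3-2.5 Angstrom in radius, hence the 2.3 Angstrom default.
#'
#' @param cloud A [skeleton_cloud()].
#' @param helices List of [helix_axis()] objects (may be empty: no-op).
#' @param radius Mask radius in Angstrom.
#' @param boundary `"inclusive"` removes points at exactly `radius`
#'   (the default reading of "within"), `"exclusive"` keeps them.
#' @return The masked [skeleton_cloud()].
#' @export
mask_helix_voxels <- function(cloud, helices, radius = 2.3,
                              boundary = c("inclusive", "exclusive")) {
  stopifnot(inherits(cloud, "skeleton_cloud"), radius > 0)
  boundary <- match.arg(boundary)
  if (inherits(helices, "helix_axis")) helices <- list(helices)
  keep <- rep(TRUE, nrow(cloud$points))
  for (h in helices) {
    d <- points_segment_distance(cloud$points, h$p, h$q)
    keep <- keep & (if (boundary == "inclusive") d > radius else d >= radius)
  }
  if (!any(keep)) {
    stop(structure(class = c("looprule_empty_skeleton", "error", "condition"),
                   list(message = "no loop skeleton remains after helix masking",
                        call = sys.call())))
  }
  skeleton_cloud(cloud$points[keep, , drop = FALSE], voxel_size = cloud$voxel_size,
                 origin = cloud$origin, source = cloud$source)
}

# Neighbour edges among `pts` (in voxel units) closer than max_edge, found by
# bucketing points into a grid of cell size max_edge so only the 27 surrounding
# cells need scanning. Returns a 2-column index matrix (i < j).
neighbor_edges <- function(pts, max_edge, strict = TRUE) {
  n <- nrow(pts)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  cell <- floor(sweep(pts, 2L, apply(pts, 2L, min)) / max_edge)
  key <- paste(cell[, 1L], cell[, 2L], cell[, 3L])
  buckets <- split(seq_len(n), key)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  # half-space of offsets (plus same cell) so each cell pair is visited once
  offs <- offs[offs[, 1L] > 0 | (offs[, 1L] == 0 & offs[, 2L] > 0) |
               (offs[, 1L] == 0 & offs[, 2L] == 0 & offs[, 3L] >= 0), , drop = FALSE]
  edges <- list()
  for (k in names(buckets)) {
    a <- buckets[[k]]
    ck <- as.integer(strsplit(k, " ")[[1]])
    for (r in seq_len(nrow(offs))) {
      o <- offs[r, ]
      if (all(o == 0L)) {
        if (length(a) < 2L) next
        cand <- t(utils::combn(a, 2L))
      } else {
        b <- buckets[[paste(ck[1] + o[1], ck[2] + o[2], ck[3] + o[3])]]
        if (is.null(b)) next
        cand <- cbind(rep(a, each = length(b)), rep(b, times = length(a)))
      }
      d <- sqrt(rowSums((pts[cand[, 1L], , drop = FALSE] -
                         pts[cand[, 2L], , drop = FALSE])^2))
      ok <- if (strict) d < max_edge else d <= max_edge
      if (any(ok)) edges[[length(edges) + 1L]] <- cand[ok, , drop = FALSE]
    }
  }
  if (length(edges) == 0L) return(matrix(integer(0), ncol = 2L))
  e <- do.call(rbind, edges)
  cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
}

#' Cluster skeleton points into local connectivity graphs
#'
#' Distances are normalised to voxel units (Angstrom / voxel size) and every
#' pair of points closer than `max_edge` is joined by an edge; the connected
#' components of the resulting graph are the local connectivity graphs (LCGs).
#' With the default bound of 2 voxel units on a unit lattice this reproduces
#' 26-connectivity (1, sqrt(2) and sqrt(3) steps connect; axial gaps of 2 do
#' not). Component labels are deterministic: ordered by decreasing size, ties
#' broken by the lexicographically smallest member point.
#'
#' @param cloud A [skeleton_cloud()].
#' @param max_edge Maximum edge length in voxel units.
#' @param strict Compare with `<` (default) rather than `<=`.
#' @return List of `lcg` objects, each with `id`, `nodes` (n x 3 matrix in
#'   Angstrom) and `edges` (2-column index matrix).
#' @export
build_lcgs <- function(cloud, max_edge = 2.0, strict = TRUE) {
  stopifnot(inherits(cloud, "skeleton_cloud"), max_edge > 0)
  pts <- cloud$points
  n <- nrow(pts)
  e <- neighbor_edges(pts / cloud$voxel_size, max_edge, strict = strict)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(e) > 0L) g <- igraph::add_edges(g, t(e))
  comp <- igraph::components(g)
  ids <- seq_len(comp$no)
  # representative = lexicographically smallest node of each component
  reps <- t(vapply(ids, function(ci) {
    m <- pts[comp$membership == ci, , drop = FALSE]
    m[lex_order(m)[1L], ]
  }, numeric(3L)))
  ord <- order(-comp$csize, reps[, 1L], reps[, 2L], reps[, 3L])
  lcgs <- vector("list", comp$no)
  for (rank in seq_along(ord)) {
    ci <- ord[rank]
    members <- which(comp$membership == ci)
    sub <- e[comp$membership[e[, 1L]] == ci, , drop = FALSE]
    remap <- integer(n)
    remap[members] <- seq_along(members)
    lcgs[[rank]] <- structure(
      list(id = sprintf("lcg%02d", rank),
           nodes = pts[members, , drop = FALSE],
           edges = cbind(remap[sub[, 1L]], remap[sub[, 2L]])),
      class = "lcg")
  }
  lcgs
}

#' @export
print.lcg <- function(x, ...) {
  cat(sprintf("LCG '%s': %d nodes, %d edges\n", x$id, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}
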