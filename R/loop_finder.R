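#' Enumerate the four helix-endpoint pairs
#'
#' For two helices, one with axis endpoints p and q and the other with r and s,
#' the loop may lie between any of the four combinations
#' \{p,r\}, \{p,s\}, \{q,r\}, \{q,s\}; which pair the loop actually connects is
#' not known in advance, so all four are examined.
#'
#' @param h1,h2 [helix_axis()] objects.
#' @return List of 4 `endpoint_pair` objects in canonical order.
#' @export
enumerate_endpoint_pairs <- function(h1, h2) {
  stopifnot(inherits(h1, "helix_axis"), inherits(h2, "helix_axis"))
  mk <- function(label, e1, e2) {
    structure(list(label = label, e1 = e1, e2 = e2), class = "endpoint_pair")
  }
  list(mk("p-r", h1$p, h2$p),
       mk("p-s", h1$p, h2$q),
       mk("q-r", h1$q, h2$p),
       mk("q-s", h1$q, h2$q))
}

#' Directed Hausdorff distance from an endpoint pair to an LCG
#'
#' `max` over the points of `z` of the `min` Euclidean distance to the nodes of
#' `b`. The direction matters: the first argument is always the (small) set of
#' helix endpoints and the second the skeleton cluster, so the value is small
#' only when *both* endpoints lie near the cluster.
#'
#' @param z An `endpoint_pair`, or a matrix/list of points (Angstrom).
#' @param b An `lcg` or a point matrix.
#' @return Distance in Angstrom.
#' @export
directed_hausdorff <- function(z, b) {
  zp <- if (inherits(z, "endpoint_pair")) rbind(z$e1, z$e2) else as_point_matrix(z)
  bp <- if (inherits(b, "lcg")) b$nodes else as_point_matrix(b)
  if (nrow(bp) == 0L) stop("directed Hausdorff distance to an empty LCG is undefined")
  max(vapply(seq_len(nrow(zp)), function(i) {
    min(sqrt(rowSums(sweep(bp, 2L, zp[i, ])^2)))
  }, numeric(1L)))
}

#' Select the best LCG for an endpoint pair
#'
#' The LCG attaining the minimum directed Hausdorff distance from the endpoint
#' pair. Ties are broken deterministically: larger node count first, then
#' smaller id.
#'
#' @param z An `endpoint_pair`.
#' @param lcgs Nonempty list of `lcg` objects.
#' @return The selected `lcg`.
#' @export
select_lcg <- function(z, lcgs) {
  stopifnot(length(lcgs) >= 1L)
  h <- vapply(lcgs, function(b) directed_hausdorff(z, b), numeric(1L))
  sizes <- vapply(lcgs, function(b) nrow(b$nodes), integer(1L))
  ids <- vapply(lcgs, function(b) b$id, character(1L))
  best <- order(h, -sizes, ids)[1L]
  lcgs[[best]]
}

# Index (into `nodes`) of the node nearest to point `p`; exact distance ties
# resolved by the lexicographically smallest node.
nearest_node <- function(nodes, p) {
  d <- sqrt(rowSums(sweep(nodes, 2L, p)^2))
  cand <- which(d == min(d))
  if (length(cand) > 1L) {
    m <- nodes[cand, , drop = FALSE]
    cand <- cand[lex_order(m)[1L]]
  }
  cand[1L]
}

#' Attach an endpoint pair to an LCG
#'
#' Each helix endpoint is joined by a new edge to its Euclidean-closest node of
#' the selected LCG. If either new edge is longer than `cutoff` (5 Angstrom by
#' default) the combination is discarded as an infeasible path; an edge of
#' exactly `cutoff` is still accepted.
#'
#' @param z An `endpoint_pair`.
#' @param lcg An `lcg`.
#' @param cutoff Maximum attachment edge length in Angstrom.
#' @return List with `nodes`, `edges`, `source_idx`, `target_idx`,
#'   `attach_lengths` and `feasible`.
#' @export
attach_endpoints <- function(z, lcg, cutoff = 5.0) {
  stopifnot(inherits(z, "endpoint_pair"), inherits(lcg, "lcg"))
  n <- nrow(lcg$nodes)
  i1 <- nearest_node(lcg$nodes, z$e1)
  i2 <- nearest_node(lcg$nodes, z$e2)
  len1 <- euclidean(z$e1, lcg$nodes[i1, ])
  len2 <- euclidean(z$e2, lcg$nodes[i2, ])
  nodes <- rbind(lcg$nodes, z$e1, z$e2)
  edges <- rbind(lcg$edges, c(n + 1L, i1), c(n + 2L, i2))
  list(nodes = nodes, edges = edges,
       source_idx = n + 1L, target_idx = n + 2L,
       attach_lengths = c(len1, len2),
       feasible = len1 <= cutoff && len2 <= cutoff)
}

#' Breadth-first-search path between two nodes of a graph
#'
#' Unweighted BFS from `source` to `target`, returning a minimum-hop path.
#' Neighbour expansion follows ascending lexicographic node coordinates, so
#' the returned path is deterministic. With `weighted = TRUE` a Dijkstra
#' search with Euclidean edge weights is used instead (an optional extension;
#' plain BFS is the default behaviour).
#'
#' @param graph List with `nodes` (n x 3 matrix) and `edges` (2-column index
#'   matrix), e.g. from [attach_endpoints()].
#' @param source,target Node indices.
#' @param weighted Use Euclidean-weighted shortest path instead of hop count.
#' @return List with `path_idx` (node indices), `vertices` (matrix), and
#'   `hops`; `NULL` if target is unreachable.
#' @export
bfs_path <- function(graph, source, target, weighted = FALSE) {
  n <- nrow(graph$nodes)
  stopifnot(source >= 1L, source <= n, target >= 1L, target <= n)
  if (weighted) {
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (nrow(graph$edges) > 0L) g <- igraph::add_edges(g, t(graph$edges))
    w <- sqrt(rowSums((graph$nodes[graph$edges[, 1L], , drop = FALSE] -
                       graph$nodes[graph$edges[, 2L], , drop = FALSE])^2))
    sp <- igraph::shortest_paths(g, from = source, to = target, weights = w)
    idx <- as.integer(sp$vpath[[1L]])
    if (length(idx) == 0L) return(NULL)
    return(list(path_idx = idx,
                vertices = graph$nodes[idx, , drop = FALSE],
                hops = length(idx) - 1L))
  }
  rank <- integer(n)
  rank[lex_order(graph$nodes)] <- seq_len(n)
  adj <- vector("list", n)
  if (nrow(graph$edges) > 0L) {
    for (r in seq_len(nrow(graph$edges))) {
      a <- graph$edges[r, 1L]; b <- graph$edges[r, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    for (i in seq_len(n)) {
      if (length(adj[[i]]) > 1L) adj[[i]] <- adj[[i]][order(rank[adj[[i]]])]
    }
  }
  parent <- integer(n)
  seen <- logical(n)
  queue <- integer(n)
  head <- 1L; tail <- 1L
  queue[1L] <- source; seen[source] <- TRUE
  while (head <= tail) {
    u <- queue[head]; head <- head + 1L
    if (u == target) break
    for (v in adj[[u]]) {
      if (!seen[v]) {
        seen[v] <- TRUE
        parent[v] <- u
        tail <- tail + 1L
        queue[tail] <- v
      }
    }
  }
  if (!seen[target]) return(NULL)
  idx <- target
  while (idx[1L] != source) idx <- c(parent[idx[1L]], idx)
  list(path_idx = idx,
       vertices = graph$nodes[idx, , drop = FALSE],
       hops = length(idx) - 1L)
}

#' Find candidate loop paths for all four endpoint pairs
#'
#' For each endpoint pair: select its best LCG by directed Hausdorff distance,
#' attach the endpoints, and trace a BFS path through the cluster. Pairs whose
#' attachment edges exceed the cutoff are reported as infeasible rather than
#' dropped.
#'
#' @param h1,h2 [helix_axis()] objects.
#' @param lcgs Nonempty list of `lcg` objects.
#' @param cutoff Attachment cutoff in Angstrom.
#' @param weighted Passed to [bfs_path()].
#' @return List of 4 `loop_path` objects (fields: `pair`, `lcg_id`,
#'   `vertices`, `attach_lengths`, `hausdorff`, `hops`, `feasible`).
#' @export
find_loop_paths <- function(h1, h2, lcgs, cutoff = 5.0, weighted = FALSE) {
  stopifnot(length(lcgs) >= 1L)
  lapply(enumerate_endpoint_pairs(h1, h2), function(z) {
    lcg <- select_lcg(z, lcgs)
    aug <- attach_endpoints(z, lcg, cutoff = cutoff)
    res <- list(pair = z, lcg_id = lcg$id,
                hausdorff = directed_hausdorff(z, lcg),
                attach_lengths = aug$attach_lengths,
                vertices = NULL, hops = NA_integer_,
                feasible = FALSE)
    if (aug$feasible) {
      bp <- bfs_path(aug, aug$source_idx, aug$target_idx, weighted = weighted)
      if (!is.null(bp)) {
        res$vertices <- bp$vertices
        res$hops <- bp$hops
        res$feasible <- TRUE
      }
    }
    structure(res, class = "loop_path")
  })
}

#' @export
print.loop_path <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf("loop path %s via %s: %d vertices, %.2f A unsimplified\n",
                x$pair$label, x$lcg_id, nrow(x$vertices), polyline_length(x$vertices)))
  } else {
    cat(sprintf("loop path %s via %s: infeasible (attach %.2f / %.2f A)\n",
                x$pair$label, x$lcg_id, x$attach_lengths[1], x$attach_lengths[2]))
  }
  invisible(x)
}
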