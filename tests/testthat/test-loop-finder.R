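h1 <- helix_axis("H1", c(0, 0, 0), c(0, 0, 10))
h2 <- helix_axis("H2", c(8, 0, 0), c(8, 0, 10))

test_that("exactly four endpoint pairs are enumerated, symmetric under helix swap", {
  pairs <- enumerate_endpoint_pairs(h1, h2)
  expect_length(pairs, 4L)
  expect_identical(vapply(pairs, `[[`, character(1), "label"),
                   c("p-r", "p-s", "q-r", "q-s"))
  swapped <- enumerate_endpoint_pairs(h2, h1)
  key <- function(z) paste(apply(rbind(z$e1, z$e2)[order(c(z$e1[1], z$e2[1])), ],
                                 1, paste, collapse = ","), collapse = "|")
  expect_setequal(vapply(pairs, key, character(1)),
                  vapply(swapped, key, character(1)))
})

test_that("directed Hausdorff matches hand-computed cases and is asymmetric", {
  z <- rbind(c(0, 0, 0), c(3, 0, 0))
  b <- rbind(c(0, 1, 0), c(3, 4, 0))
  expect_equal(directed_hausdorff(z, b), sqrt(10))
  expect_equal(directed_hausdorff(b, z), 4)  # direction matters
  expect_equal(directed_hausdorff(rbind(c(1, 2, 3)), rbind(c(4, 6, 3))), 5)
  expect_equal(directed_hausdorff(b, rbind(b, c(50, 0, 0))), 0)  # z subset of b
})

test_that("directed Hausdorff equals the brute-force double loop on random fixtures", {
  set.seed(51)
  for (i in 1:100) {
    z <- matrix(runif(6, -10, 10), ncol = 3)
    b <- matrix(runif(3 * sample(1:40, 1), -10, 10), ncol = 3)
    expect_identical(directed_hausdorff(z, b), oracle_hausdorff(z, b))
  }
})

test_that("LCG selection takes the argmin over exhaustive evaluation, with deterministic ties", {
  set.seed(52)
  z <- enumerate_endpoint_pairs(h1, h2)[[3]]
  for (i in 1:20) {
    lcgs <- lapply(1:5, function(k) {
      ctr <- runif(3, -20, 20)
      structure(list(id = sprintf("lcg%02d", k),
                     nodes = sweep(matrix(rnorm(30), ncol = 3), 2, ctr, `+`),
                     edges = matrix(integer(0), ncol = 2)),
                class = "lcg")
    })
    h <- vapply(lcgs, function(b) oracle_hausdorff(rbind(z$e1, z$e2), b$nodes),
                numeric(1))
    expect_identical(select_lcg(z, lcgs)$id, lcgs[[which.min(h)]]$id)
  }
  # exact tie: two identical clusters -> smaller id wins
  twin <- list(
    structure(list(id = "lcg02", nodes = rbind(c(1, 1, 1)), edges = matrix(integer(0), ncol = 2)), class = "lcg"),
    structure(list(id = "lcg01", nodes = rbind(c(1, 1, 1)), edges = matrix(integer(0), ncol = 2)), class = "lcg"))
  expect_identical(select_lcg(z, twin)$id, "lcg01")
})

test_that("selection with clustered decoys picks the cluster spanning both endpoints", {
  # six clusters; only one is near *both* endpoints of the pair
  z <- enumerate_endpoint_pairs(helix_axis("A", c(-10, 0, 0), c(0, 0, 0)),
                                helix_axis("B", c(10, 0, 0), c(20, 0, 0)))[[3]] # q-r: (0,0,0)-(10,0,0)
  arc <- cbind(seq(0, 10, by = 0.5), 3 * sin(pi * seq(0, 1, by = 0.05)), 0)
  near1 <- sweep(matrix(rnorm(30, sd = 0.5), ncol = 3), 2, c(0, 2, 0), `+`)   # near e1 only
  far <- sweep(matrix(rnorm(30, sd = 0.5), ncol = 3), 2, c(30, 0, 0), `+`)
  mk <- function(id, nodes) structure(list(id = id, nodes = nodes,
                                           edges = matrix(integer(0), ncol = 2)),
                                      class = "lcg")
  lcgs <- list(mk("lcg01", arc), mk("lcg02", near1), mk("lcg03", far))
  expect_identical(select_lcg(z, lcgs)$id, "lcg01")
})

test_that("endpoint attachment respects the 5 A cutoff boundary", {
  lcg <- structure(list(id = "lcg01",
                        nodes = rbind(c(0, 0, 1), c(0, 0, 2)),
                        edges = rbind(c(1L, 2L))), class = "lcg")
  mkpair <- function(e1, e2) structure(list(label = "q-r", e1 = e1, e2 = e2),
                                       class = "endpoint_pair")
  expect_true(attach_endpoints(mkpair(c(0, 0, 0), c(0, 0, 3)), lcg)$feasible)
  expect_true(attach_endpoints(mkpair(c(0, 0, -4), c(0, 0, 3)), lcg)$feasible)   # exactly 5
  expect_false(attach_endpoints(mkpair(c(0, 0, -4.1), c(0, 0, 3)), lcg)$feasible) # 5.1
  aug <- attach_endpoints(mkpair(c(0, 0, 0), c(0, 0, 3)), lcg)
  expect_equal(aug$attach_lengths, c(1, 1))
  expect_equal(nrow(aug$nodes), 4L)
})

test_that("BFS returns minimum-hop paths matching an independent oracle", {
  # straight chain of 5 voxels between the endpoints: unique path, in order
  chain <- rbind(c(0, 0, 1), c(0, 0, 2), c(0, 0, 3), c(0, 0, 4), c(0, 0, 5))
  lcg <- structure(list(id = "lcg01", nodes = chain,
                        edges = cbind(1:4, 2:5)), class = "lcg")
  z <- structure(list(label = "q-r", e1 = c(0, 0, 0), e2 = c(0, 0, 6)),
                 class = "endpoint_pair")
  aug <- attach_endpoints(z, lcg)
  bp <- bfs_path(aug, aug$source_idx, aug$target_idx)
  expect_equal(unname(bp$vertices),
               rbind(c(0, 0, 0), chain, c(0, 0, 6)))
  expect_equal(bp$hops, 6L)

  # 2-hop vs 4-hop alternative routes
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),           # short route
                 c(0, 1, 0), c(1, 2, 0), c(2, 1, 0))           # long detour
  g <- list(nodes = nodes, edges = rbind(c(1L, 2L), c(2L, 3L),
                                         c(1L, 4L), c(4L, 5L), c(5L, 6L), c(6L, 3L)))
  bp <- bfs_path(g, 1L, 3L)
  expect_equal(bp$hops, 2L)
  expect_equal(bp$path_idx, c(1L, 2L, 3L))

  # random graphs: hop count equals igraph's unweighted shortest-path distance
  set.seed(53)
  for (i in 1:30) {
    n <- sample(8:40, 1)
    nodes <- matrix(runif(3 * n, 0, 10), ncol = 3)
    e <- looprule:::neighbor_edges(nodes, 3.0)
    if (nrow(e) == 0) next
    g <- list(nodes = nodes, edges = e)
    ig <- igraph::graph_from_edgelist(e, directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0, n - igraph::vcount(ig)))
    dmat <- igraph::distances(ig)
    s <- sample(n, 1); t <- sample(n, 1)
    bp <- bfs_path(g, s, t)
    if (is.infinite(dmat[s, t])) {
      expect_null(bp)
    } else {
      expect_equal(bp$hops, unname(dmat[s, t]))
    }
  }
})

test_that("BFS follows the correct branch of a Y-shaped skeleton", {
  # trunk from (0,0,0) up to (0,0,3), then branches to +x and +y
  trunk <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2), c(0, 0, 3))
  bx <- rbind(c(1, 0, 4), c(2, 0, 5), c(3, 0, 6))
  by <- rbind(c(0, 1, 4), c(0, 2, 5))
  nodes <- rbind(trunk, bx, by)
  e <- looprule:::neighbor_edges(nodes, 2.0)
  bp <- bfs_path(list(nodes = nodes, edges = e), 1L, 7L)  # to the +x branch tip
  expect_equal(unname(bp$vertices), rbind(trunk, bx))     # off-branch excluded
  # oracle: minimum hop count over all simple paths
  ig <- igraph::graph_from_edgelist(e, directed = FALSE)
  asp <- igraph::all_simple_paths(ig, from = 1, to = 7)
  expect_equal(bp$hops, min(lengths(asp)) - 1L)
})

test_that("find_loop_paths reports four results, invariant to LCG order, infeasible when far", {
  hlh <- generate_hlh(5, seed = 61, decoy_clusters = 2)
  lcgs <- build_lcgs(hlh$cloud)
  paths <- find_loop_paths(hlh$helices[[1]], hlh$helices[[2]], lcgs)
  expect_length(paths, 4L)
  labels <- vapply(paths, function(p) p$pair$label, character(1))
  expect_true(paths[[which(labels == hlh$true_pair_label)]]$feasible)
  perm <- find_loop_paths(hlh$helices[[1]], hlh$helices[[2]], rev(lcgs))
  for (i in 1:4) {
    expect_identical(perm[[i]]$lcg_id, paths[[i]]$lcg_id)
    expect_equal(perm[[i]]$vertices, paths[[i]]$vertices)
  }
  # everything farther than the cutoff: all four infeasible
  far1 <- helix_axis("F1", c(100, 0, 0), c(100, 0, 10))
  far2 <- helix_axis("F2", c(120, 0, 0), c(120, 0, 10))
  none <- find_loop_paths(far1, far2, lcgs)
  expect_false(any(vapply(none, `[[`, logical(1), "feasible")))
})
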