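test_that("helix masking removes points within the radius of the finite axis", {
  axis <- helix_axis("H", c(0, 0, 0), c(0, 0, 10))
  pts <- rbind(c(2, 0, 5),    # 2.0 A from the axis: removed
               c(3, 0, 5),    # 3.0 A: kept
               c(2.3, 0, 5),  # exactly at the radius: removed (inclusive)
               c(0, 0, 14))   # 4 A beyond the axis end: kept (finite segment)
  cloud <- skeleton_cloud(pts)
  masked <- mask_helix_voxels(cloud, list(axis))
  expect_equal(unname(masked$points), pts[c(2, 4), ])
  excl <- mask_helix_voxels(cloud, list(axis), boundary = "exclusive")
  expect_equal(unname(excl$points), pts[c(2, 3, 4), ])  # the boundary point survives
})

test_that("masking with no helices is a no-op and masking is idempotent", {
  set.seed(41)
  cloud <- skeleton_cloud(matrix(runif(600, -15, 15), ncol = 3))
  expect_equal(mask_helix_voxels(cloud, list())$points, cloud$points)
  helices <- list(helix_axis("A", c(0, 0, 0), c(10, 0, 0)),
                  helix_axis("B", c(0, 5, 0), c(0, 5, 10)))
  once <- mask_helix_voxels(cloud, helices)
  twice <- mask_helix_voxels(once, helices)
  expect_equal(twice$points, once$points)
})

test_that("masking agrees with a brute-force per-point distance check", {
  set.seed(42)
  pts <- matrix(runif(600, -15, 15), ncol = 3)
  helices <- list(helix_axis("A", c(-5, 0, 0), c(5, 0, 0)),
                  helix_axis("B", c(0, -5, 3), c(0, 5, 3)))
  masked <- mask_helix_voxels(skeleton_cloud(pts), helices)
  keep <- vapply(seq_len(nrow(pts)), function(i) {
    all(vapply(helices, function(h) {
      point_segment_distance(pts[i, ], h$p, h$q) > 2.3
    }, logical(1)))
  }, logical(1))
  expect_equal(unname(masked$points), pts[keep, , drop = FALSE])
})

test_that("fully masked skeleton raises the empty-skeleton condition", {
  cloud <- skeleton_cloud(rbind(c(0, 1, 5), c(0, 0, 3)))
  expect_error(mask_helix_voxels(cloud, list(helix_axis("H", c(0, 0, 0), c(0, 0, 10)))),
               class = "looprule_empty_skeleton")
})

test_that("edge bound in voxel units is strict and clusters accordingly", {
  # 26-neighbour steps (1, sqrt 2, sqrt 3) connect under l < 2 ...
  cloud <- skeleton_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 1)))
  expect_length(build_lcgs(cloud), 1L)
  # ... but an axial gap of exactly 2 does not
  two <- skeleton_cloud(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_length(build_lcgs(two), 2L)
  expect_length(build_lcgs(two, strict = FALSE), 1L)
  # voxel units: the same gap at voxel_size 2 is only 1 voxel unit wide
  expect_length(build_lcgs(skeleton_cloud(rbind(c(0, 0, 0), c(2, 0, 0)),
                                          voxel_size = 2)), 1L)
  # single isolated point still forms a 1-node LCG
  expect_length(build_lcgs(skeleton_cloud(matrix(c(5, 5, 5), ncol = 3))), 1L)
})

test_that("LCG components match an all-pairs union-find oracle and partition the cloud", {
  set.seed(43)
  pts <- matrix(runif(1500, 0, 25), ncol = 3)
  cloud <- skeleton_cloud(pts, voxel_size = 1.3)
  lcgs <- build_lcgs(cloud, max_edge = 2.0)
  labels <- oracle_components(pts, 1.3, 2.0)
  mine <- integer(nrow(pts))
  for (k in seq_along(lcgs)) {
    for (r in seq_len(nrow(lcgs[[k]]$nodes))) {
      i <- which(pts[, 1] == lcgs[[k]]$nodes[r, 1] &
                 pts[, 2] == lcgs[[k]]$nodes[r, 2] &
                 pts[, 3] == lcgs[[k]]$nodes[r, 3])
      mine[i] <- k
    }
  }
  expect_true(all(mine > 0L))  # partition: every point in exactly one LCG
  expect_equal(sum(vapply(lcgs, function(l) nrow(l$nodes), integer(1))), nrow(pts))
  expect_identical(canonical_partition(mine), canonical_partition(labels))
  # every edge respects the bound, in voxel units
  for (l in lcgs) {
    if (nrow(l$edges) == 0) next
    d <- sqrt(rowSums((l$nodes[l$edges[, 1], , drop = FALSE] -
                       l$nodes[l$edges[, 2], , drop = FALSE])^2)) / 1.3
    expect_true(all(d < 2.0))
  }
})

test_that("increasing the edge bound never increases the number of LCGs", {
  set.seed(44)
  cloud <- skeleton_cloud(matrix(runif(900, 0, 20), ncol = 3))
  counts <- vapply(c(0.5, 1, 1.5, 2, 3, 5),
                   function(me) length(build_lcgs(cloud, max_edge = me)),
                   integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("on a unit lattice the default rule reproduces 26-connectivity", {
  set.seed(45)
  idx <- unique(matrix(sample(0:7, 900, replace = TRUE), ncol = 3))
  cloud <- skeleton_cloud(idx)
  lcgs <- build_lcgs(cloud)
  # 26-connectivity oracle: Chebyshev distance 1
  n <- nrow(idx)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (max(abs(idx[i, ] - idx[j, ])) == 1) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  labels <- vapply(seq_len(n), find, integer(1))
  mine <- integer(n)
  for (k in seq_along(lcgs)) {
    for (r in seq_len(nrow(lcgs[[k]]$nodes))) {
      i <- which(idx[, 1] == lcgs[[k]]$nodes[r, 1] &
                 idx[, 2] == lcgs[[k]]$nodes[r, 2] &
                 idx[, 3] == lcgs[[k]]$nodes[r, 3])
      mine[i] <- k
    }
  }
  expect_identical(canonical_partition(mine), canonical_partition(labels))
})
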