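# Independent reference implementations used as oracles. These deliberately
# take the naive route (plain double loops, direct recursion) so they share no
# code with the package internals they check.

# Brute-force directed Hausdorff: explicit double loop over all point pairs.
oracle_hausdorff <- function(z, b) {
  best <- -Inf
  for (i in seq_len(nrow(z))) {
    dmin <- Inf
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum((z[i, ] - b[j, ])^2))
      if (d < dmin) dmin <- d
    }
    if (dmin > best) best <- dmin
  }
  best
}

# Naive recursive Douglas-Peucker, written straight from the textbook
# description: keep-indices of the simplified polyline.
oracle_dp_keep <- function(v, eps) {
  n <- nrow(v)
  if (n <= 2L) return(seq_len(n))
  a <- v[1L, ]; b <- v[n, ]
  dmax <- -1; imax <- 0L
  for (k in 2L:(n - 1L)) {
    ab <- b - a
    if (sum(ab^2) == 0) {
      d <- sqrt(sum((v[k, ] - a)^2))
    } else {
      w <- v[k, ] - a
      cr <- c(w[2] * ab[3] - w[3] * ab[2],
              w[3] * ab[1] - w[1] * ab[3],
              w[1] * ab[2] - w[2] * ab[1])
      d <- sqrt(sum(cr^2) / sum(ab^2))
    }
    if (d > dmax) { dmax <- d; imax <- k }
  }
  if (dmax > eps) {
    left <- oracle_dp_keep(v[1:imax, , drop = FALSE], eps)
    right <- oracle_dp_keep(v[imax:n, , drop = FALSE], eps)
    c(left, imax - 1L + right[-1L])
  } else {
    c(1L, n)
  }
}

oracle_dp <- function(v, eps) v[oracle_dp_keep(v, eps), , drop = FALSE]

# All-pairs union-find over the full O(N^2) distance matrix: component label
# per point under the "< max_edge in voxel units" rule.
oracle_components <- function(pts, voxel_size, max_edge, strict = TRUE) {
  n <- nrow(pts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- sqrt(sum((pts[i, ] - pts[j, ])^2)) / voxel_size
      ok <- if (strict) d < max_edge else d <= max_edge
      if (ok) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1L))
}

# Canonicalise a component labelling as a sorted list of sorted member sets.
canonical_partition <- function(labels) {
  parts <- unname(split(seq_along(labels), labels))
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, `[`, integer(1L), 1L))]
}

# Random jagged polyline for simplification tests.
random_polyline <- function(n, scale = 5) {
  matrix(stats::runif(3L * n, -scale, scale), ncol = 3L)
}

# Random rigid rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9L), 3L))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

benchmark_table <- function() {
  utils::read.table(system.file("extdata", "simulated_hlh_benchmark.tsv",
                                package = "looprule"),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
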