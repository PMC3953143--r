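# Evaluate a cubic Bezier curve (4 x 3 control matrix) at parameters t.
bezier_point <- function(ctrl, t) {
  b0 <- (1 - t)^3; b1 <- 3 * (1 - t)^2 * t; b2 <- 3 * (1 - t) * t^2; b3 <- t^3
  cbind(b0 * ctrl[1, 1] + b1 * ctrl[2, 1] + b2 * ctrl[3, 1] + b3 * ctrl[4, 1],
        b0 * ctrl[1, 2] + b1 * ctrl[2, 2] + b2 * ctrl[3, 2] + b3 * ctrl[4, 2],
        b0 * ctrl[1, 3] + b1 * ctrl[2, 3] + b2 * ctrl[3, 3] + b3 * ctrl[4, 3])
}

bezier_speed <- function(ctrl, t) {
  d1 <- ctrl[2, ] - ctrl[1, ]; d2 <- ctrl[3, ] - ctrl[2, ]; d3 <- ctrl[4, ] - ctrl[3, ]
  vx <- 3 * ((1 - t)^2 * d1[1] + 2 * (1 - t) * t * d2[1] + t^2 * d3[1])
  vy <- 3 * ((1 - t)^2 * d1[2] + 2 * (1 - t) * t * d2[2] + t^2 * d3[2])
  vz <- 3 * ((1 - t)^2 * d1[3] + 2 * (1 - t) * t * d2[3] + t^2 * d3[3])
  sqrt(vx^2 + vy^2 + vz^2)
}

#' Arc length of a cubic Bezier curve
#'
#' Numerically integrated with adaptive quadrature to a relative tolerance of
#' 1e-9; serves as the analytic ground truth for synthetic loop curves.
#'
#' @param ctrl 4 x 3 matrix of control points (Angstrom).
#' @param t0,t1 Parameter range (defaults full curve).
#' @return Arc length in Angstrom.
#' @export
bezier_arc_length <- function(ctrl, t0 = 0, t1 = 1) {
  stopifnot(is.matrix(ctrl), nrow(ctrl) == 4L, ncol(ctrl) == 3L)
  stats::integrate(function(t) bezier_speed(ctrl, t), t0, t1,
                   rel.tol = 1e-9, subdivisions = 500L)$value
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic helix-loop-helix skeleton with known loop length
#'
#' Builds two straight helix axis segments joined by a smooth cubic Bezier
#' loop whose analytic arc length is exactly `3.8 * (n_loop_residues + 1)`
#' Angstrom (the sequence expectation for a loop of that many residues). The
#' curve is sampled at no more than a quarter of the voxel size, optionally
#' jittered (Gaussian, before snapping) and snapped to the cubic lattice with
#' duplicate removal, and points within 2.3 Angstrom of either helix axis are
#' removed, so fixtures look like a post-mask loop skeleton. Optional decoy
#' clusters (placed at least 8 Angstrom from the loop-bracketing endpoints)
#' and sparse uniform noise points (at least 5 Angstrom from everything)
#' emulate segmentation clutter.
#'
#' The loop departs each helix endpoint tangent to that helix's axis, so the
#' true endpoint pair is always `"q-r"` (second endpoint of helix H1, first of
#' helix H2).
#'
#' @param n_loop_residues Number of residues on the loop (>= 1).
#' @param voxel_size Lattice spacing in Angstrom.
#' @param lattice_snap Snap curve samples to the voxel lattice.
#' @param decoy_clusters Number of decoy point clusters.
#' @param noise_points Maximum number of isolated noise points.
#' @param jitter_sd Gaussian jitter SD in Angstrom (applied before snapping).
#' @param seed RNG seed; identical seeds give identical fixtures.
#' @param helix_length Axis length of each flanking helix in Angstrom.
#' @return Object of class `synthetic_hlh` with fields `helices` (list of two
#'   [helix_axis()]), `cloud` ([skeleton_cloud()]), `true_pair_label`,
#'   `true_loop_length`, `true_lcg_points`, `ctrl` (Bezier control points),
#'   `n_loop_residues`, `seed`, and the generator parameters.
#' @export
generate_hlh <- function(n_loop_residues, voxel_size = 1.0, lattice_snap = TRUE,
                         decoy_clusters = 0L, noise_points = 0L, jitter_sd = 0,
                         seed = 1L, helix_length = 8.0) {
  stopifnot(n_loop_residues >= 1L, voxel_size > 0, jitter_sd >= 0)
  target <- expected_length(n_loop_residues)
  with_seed(seed, {
    # unit-span hairpin control polygon with seeded shape variation
    q0 <- c(-0.5, 0, 0); r0 <- c(0.5, 0, 0)
    p1 <- q0 + c(stats::runif(1, -0.08, 0.08), stats::runif(1, 0.35, 0.60),
                 stats::runif(1, -0.12, 0.12))
    p2 <- r0 + c(stats::runif(1, -0.08, 0.08), stats::runif(1, 0.35, 0.60),
                 stats::runif(1, -0.12, 0.12))
    ctrl <- rbind(q0, p1, p2, r0)
    ctrl <- ctrl * (target / bezier_arc_length(ctrl))  # exact arc length
    q <- ctrl[1, ]; r <- ctrl[4, ]
    t0 <- ctrl[2, ] - ctrl[1, ]; t0 <- t0 / sqrt(sum(t0^2))
    t1 <- ctrl[4, ] - ctrl[3, ]; t1 <- t1 / sqrt(sum(t1^2))
    h1 <- helix_axis("H1", q - helix_length * t0, q)  # q is the loop-side end
    h2 <- helix_axis("H2", r, r + helix_length * t1)  # r is the loop-side end

    spacing <- 0.25 * voxel_size
    m <- max(32L, ceiling(2 * target / spacing))
    samp <- bezier_point(ctrl, seq(0, 1, length.out = m))
    if (jitter_sd > 0) {
      samp <- samp + matrix(stats::rnorm(length(samp), sd = jitter_sd), ncol = 3L)
    }
    if (lattice_snap) {
      samp <- round(samp / voxel_size) * voxel_size
      samp <- unique(samp)
    }
    d1 <- points_segment_distance(samp, h1$p, h1$q)
    d2 <- points_segment_distance(samp, h2$p, h2$q)
    loop_pts <- samp[d1 > 2.3 & d2 > 2.3, , drop = FALSE]
    if (nrow(loop_pts) < 2L) {
      stop("infeasible geometry: loop too short to clear the 2.3 A helix mask; increase n")
    }
    near1 <- min(sqrt(rowSums(sweep(loop_pts, 2L, q)^2)))
    near2 <- min(sqrt(rowSums(sweep(loop_pts, 2L, r)^2)))
    if (near1 > 5 || near2 > 5) {
      stop("infeasible geometry: loop skeleton does not come within the 5 A attach cutoff")
    }

    pts <- loop_pts
    centre <- (q + r) / 2
    for (k in seq_len(decoy_clusters)) {
      for (try in 1:200) {
        dir <- stats::rnorm(3L); dir <- dir / sqrt(sum(dir^2))
        ctr <- centre + stats::runif(1, 9, 16) * dir
        if (euclidean(ctr, q) >= 8 && euclidean(ctr, r) >= 8 &&
            min(sqrt(rowSums(sweep(loop_pts, 2L, ctr)^2))) >= 6) break
        ctr <- NULL
      }
      if (is.null(ctr)) next
      blob <- sweep(matrix(stats::rnorm(45L, sd = 1.0), ncol = 3L), 2L, ctr, `+`)
      if (lattice_snap) blob <- unique(round(blob / voxel_size) * voxel_size)
      pts <- rbind(pts, blob)
    }
    if (noise_points > 0L) {
      lo <- apply(pts, 2L, min) - 10; hi <- apply(pts, 2L, max) + 10
      added <- 0L
      for (try in seq_len(50L * noise_points)) {
        if (added >= noise_points) break
        cand <- stats::runif(3L, lo, hi)
        if (min(sqrt(rowSums(sweep(pts, 2L, cand)^2))) >= 5 &&
            euclidean(cand, q) >= 5 && euclidean(cand, r) >= 5) {
          if (lattice_snap) cand <- round(cand / voxel_size) * voxel_size
          pts <- rbind(pts, cand)
          added <- added + 1L
        }
      }
    }
    structure(list(
      helices = list(h1, h2),
      cloud = skeleton_cloud(pts, voxel_size = voxel_size, source = "memory"),
      true_pair_label = "q-r",
      true_loop_length = target,
      true_lcg_points = loop_pts,
      ctrl = ctrl,
      n_loop_residues = as.integer(n_loop_residues),
      seed = as.integer(seed),
      params = list(voxel_size = voxel_size, lattice_snap = lattice_snap,
                    decoy_clusters = as.integer(decoy_clusters),
                    noise_points = as.integer(noise_points),
                    jitter_sd = jitter_sd, helix_length = helix_length)),
      class = "synthetic_hlh")
  })
}

#' @export
print.synthetic_hlh <- function(x, ...) {
  cat(sprintf(paste0("synthetic HLH: %d loop residues, true length %.2f A, ",
                     "%d skeleton points (%d on the loop), seed %d\n"),
              x$n_loop_residues, x$true_loop_length, nrow(x$cloud$points),
              nrow(x$true_lcg_points), x$seed))
  invisible(x)
}

#' Write a synthetic fixture to disk
#'
#' Emits the skeleton in both the MRC and plain-text dialects (the MRC volume
#' only when the cloud sits on the lattice), the helix annotation JSON, and a
#' ground-truth JSON with the true loop length, true endpoint pair, seed and
#' generator parameters. Everything round-trips through the package readers.
#'
#' @param hlh A `synthetic_hlh`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_fixture <- function(hlh, dir) {
  stopifnot(inherits(hlh, "synthetic_hlh"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(text = file.path(dir, "skeleton.txt"),
             helices = file.path(dir, "helices.json"),
             truth = file.path(dir, "truth.json"))
  write_skeleton_text(hlh$cloud, files[["text"]])
  write_helices(hlh$helices, files[["helices"]])
  jsonlite::write_json(list(true_loop_length = hlh$true_loop_length,
                            true_pair = hlh$true_pair_label,
                            n_loop_residues = hlh$n_loop_residues,
                            seed = hlh$seed, params = hlh$params),
                       files[["truth"]], auto_unbox = TRUE, digits = NA)
  if (isTRUE(hlh$params$lattice_snap)) {
    files[["mrc"]] <- file.path(dir, "skeleton.mrc")
    write_skeleton_mrc(hlh$cloud, files[["mrc"]])
  }
  files
}
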