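#' Estimate the loop length between two helices along a skeleton
#'
#' Runs the full measurement pipeline on a skeleton point cloud and two
#' detected helix axes: mask skeleton voxels inside the helix regions, cluster
#' the remainder into local connectivity graphs (LCGs), and for each of the
#' four helix-endpoint pairs select the nearest LCG by directed Hausdorff
#' distance, attach the endpoints, trace a BFS path and measure its
#' Douglas-Peucker-simplified length. With a fixed `epsilon` each pair is
#' measured once; otherwise the tolerance is swept over a grid and, when a
#' loop residue count `n_residues` is given, the measurement closest to the
#' expected length `3.8 (n + 1)` is reported together with its epsilon.
#'
#' @param skeleton A [skeleton_cloud()].
#' @param helices List of exactly two [helix_axis()] objects.
#' @param n_residues Optional number of residues on the loop, enabling the
#'   expected-length comparison columns.
#' @param mask_radius Helix mask radius in Angstrom (default 2.3).
#' @param mask_boundary Passed to [mask_helix_voxels()].
#' @param max_edge LCG edge bound in voxel units (default 2).
#' @param edge_strict Compare edge lengths with `<` (default) or `<=`.
#' @param attach_cutoff Endpoint attachment cutoff in Angstrom (default 5).
#' @param epsilon Fixed simplification tolerance; `NULL` (default) sweeps.
#' @param sweep Numeric `c(min, max, step)` for the tolerance sweep
#'   (default `c(0, 6, 0.05)`).
#' @param weighted Use Euclidean-weighted paths instead of plain BFS.
#' @return Object of class `loop_length_fit`: a list with `reports` (one row
#'   per endpoint pair), `paths`, `sweeps`, `lcgs`, `masked_cloud`, `helices`
#'   and `config`.
#' @examples
#' hlh <- generate_hlh(3, seed = 7)
#' fit <- estimate_loop_length(hlh$cloud, hlh$helices, n_residues = 3)
#' fit
#' @export
estimate_loop_length <- function(skeleton, helices, n_residues = NULL,
                                 mask_radius = 2.3,
                                 mask_boundary = "inclusive",
                                 max_edge = 2.0, edge_strict = TRUE,
                                 attach_cutoff = 5.0,
                                 epsilon = NULL, sweep = c(0, 6, 0.05),
                                 weighted = FALSE) {
  stopifnot(inherits(skeleton, "skeleton_cloud"))
  if (inherits(helices, "helix_axis")) helices <- list(helices)
  if (length(helices) != 2L) {
    stop(structure(class = c("looprule_input_error", "error", "condition"),
                   list(message = "loop measurement needs exactly two helices",
                        call = sys.call())))
  }
  masked <- mask_helix_voxels(skeleton, helices, radius = mask_radius,
                              boundary = mask_boundary)
  lcgs <- build_lcgs(masked, max_edge = max_edge, strict = edge_strict)
  paths <- find_loop_paths(helices[[1L]], helices[[2L]], lcgs,
                           cutoff = attach_cutoff, weighted = weighted)
  expected <- if (is.null(n_residues)) NULL else expected_length(n_residues)

  sweeps <- vector("list", 4L)
  rows <- vector("list", 4L)
  for (i in seq_along(paths)) {
    pp <- paths[[i]]
    row <- list(pair = pp$pair$label, feasible = pp$feasible,
                expected = if (is.null(expected)) NA_real_ else expected,
                measured = NA_real_, diff = NA_real_, rel_err = NA_real_,
                epsilon = NA_real_, lcg_id = pp$lcg_id,
                hausdorff = pp$hausdorff,
                attach_1 = pp$attach_lengths[1L], attach_2 = pp$attach_lengths[2L],
                n_before = NA_integer_, n_after = NA_integer_)
    if (pp$feasible) {
      row$n_before <- nrow(pp$vertices)
      if (!is.null(epsilon)) {
        simp <- douglas_peucker(pp$vertices, epsilon)
        row$epsilon <- epsilon
        row$measured <- polyline_length(simp)
        row$n_after <- nrow(simp)
      } else {
        sw <- epsilon_sweep(pp, eps_min = sweep[1L], eps_max = sweep[2L],
                            step = sweep[3L], expected = expected)
        sweeps[[i]] <- sw
        eps_used <- if (!is.na(sw$best_epsilon)) sw$best_epsilon else sweep[1L]
        simp <- douglas_peucker(pp$vertices, eps_used)
        row$epsilon <- eps_used
        row$measured <- polyline_length(simp)
        row$n_after <- nrow(simp)
      }
      if (!is.null(expected)) {
        em <- error_metrics(row$measured, expected)
        row$diff <- em$diff
        row$rel_err <- em$rel_err
      }
    }
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  reports <- do.call(rbind, rows)
  structure(list(reports = reports, paths = paths, sweeps = sweeps,
                 lcgs = lcgs, masked_cloud = masked, helices = helices,
                 config = list(n_residues = n_residues, mask_radius = mask_radius,
                               mask_boundary = mask_boundary, max_edge = max_edge,
                               edge_strict = edge_strict,
                               attach_cutoff = attach_cutoff, epsilon = epsilon,
                               sweep = sweep, weighted = weighted)),
            class = "loop_length_fit")
}

#' @export
print.loop_length_fit <- function(x, digits = 4L, ...) {
  cat(sprintf("Loop length estimate (%d LCGs from %d masked skeleton points)\n",
              length(x$lcgs), nrow(x$masked_cloud$points)))
  df <- x$reports[, c("pair", "feasible", "expected", "measured", "diff",
                      "rel_err", "epsilon", "lcg_id")]
  print(format(df, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.loop_length_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.loop_length_fit")
}

#' @export
print.summary.loop_length_fit <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nPer-pair selection detail:\n")
  df <- fit$reports[, c("pair", "lcg_id", "hausdorff", "attach_1", "attach_2",
                        "n_before", "n_after")]
  print(format(df, digits = 4L), row.names = FALSE)
  cat(sprintf("\nLCG sizes: %s\n",
              paste(vapply(fit$lcgs, function(l) nrow(l$nodes), integer(1L)),
                    collapse = ", ")))
  invisible(x)
}

#' Plot the tolerance step function of a loop-length fit
#'
#' Draws the measured length versus epsilon for every feasible endpoint pair
#' that was swept, with the expected length (if any) as a dashed line.
#'
#' @param x A `loop_length_fit`.
#' @param pairs Pair labels to draw (default: all swept pairs).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.loop_length_fit <- function(x, pairs = NULL, ...) {
  swept <- which(!vapply(x$sweeps, is.null, logical(1L)))
  if (!is.null(pairs)) {
    swept <- swept[x$reports$pair[swept] %in% pairs]
  }
  if (length(swept) == 0L) stop("no epsilon sweeps to plot (fixed-epsilon fit?)")
  rng <- range(unlist(lapply(x$sweeps[swept], `[[`, "measured")))
  exp_len <- x$reports$expected[1L]
  if (!is.na(exp_len)) rng <- range(rng, exp_len)
  first <- x$sweeps[[swept[1L]]]
  graphics::plot(first$epsilon, first$measured, type = "s", ylim = rng,
                 xlab = expression(epsilon ~ "(Å)"),
                 ylab = "measured length (Å)", ...)
  if (length(swept) > 1L) {
    for (j in seq_along(swept)[-1L]) {
      s <- x$sweeps[[swept[j]]]
      graphics::lines(s$epsilon, s$measured, type = "s", lty = j)
    }
  }
  if (!is.na(exp_len)) graphics::abline(h = exp_len, lty = 3L)
  graphics::legend("topright", legend = x$reports$pair[swept],
                   lty = seq_along(swept), bty = "n")
  invisible(x)
}
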