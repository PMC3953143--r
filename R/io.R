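#' Skeleton point cloud
#'
#' Container for a set of skeleton voxel centres in Angstrom, together with the
#' lattice metadata (voxel size and origin) needed to convert between voxel
#' indices and physical coordinates.
#'
#' @param points Numeric n x 3 matrix of coordinates in Angstrom.
#' @param voxel_size Isotropic lattice spacing in Angstrom per voxel (> 0).
#' @param origin Numeric length-3 origin in Angstrom.
#' @param source One of "map", "text" or "memory".
#' @return An object of class `skeleton_cloud`.
#' @export
skeleton_cloud <- function(points, voxel_size = 1.0, origin = c(0, 0, 0),
                           source = "memory") {
  points <- as_point_matrix(points)
  if (nrow(points) == 0L) stop("empty skeleton: a skeleton cloud needs at least one point")
  if (!is.finite(voxel_size) || voxel_size <= 0) stop("voxel_size must be > 0")
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, voxel_size = voxel_size,
                 origin = as.numeric(origin), source = source),
            class = "skeleton_cloud")
}

#' @export
print.skeleton_cloud <- function(x, ...) {
  cat(sprintf("skeleton cloud: %d points, voxel size %g A, source '%s'\n",
              nrow(x$points), x$voxel_size, x$source))
  invisible(x)
}

#' Helix central-axis segment
#'
#' A detected alpha-helix is represented by the two endpoints of its central
#' axis, in Angstrom. The axis must have positive length.
#'
#' @param id Label for the helix.
#' @param p,q Numeric length-3 axis endpoints in Angstrom.
#' @return An object of class `helix_axis`.
#' @export
helix_axis <- function(id, p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  stopifnot(length(p) == 3L, length(q) == 3L, all(is.finite(c(p, q))))
  if (all(p == q)) stop(sprintf("degenerate axis for helix '%s': p equals q", id))
  structure(list(id = as.character(id), p = p, q = q), class = "helix_axis")
}

#' @export
print.helix_axis <- function(x, ...) {
  cat(sprintf("helix '%s': (%g, %g, %g) -- (%g, %g, %g), length %.2f A\n",
              x$id, x$p[1], x$p[2], x$p[3], x$q[1], x$q[2], x$q[3],
              euclidean(x$p, x$q)))
  invisible(x)
}

#' Read a skeleton point cloud from a plain-text XYZ file
#'
#' One point per line, whitespace- or comma-separated x y z in Angstrom.
#' Lines starting with `#` are comments; a `#voxel_size <float>` directive sets
#' the lattice spacing (default 1.0) and `#origin <x> <y> <z>` sets the origin.
#'
#' @param path File to read.
#' @return A [skeleton_cloud()] with `source = "text"`.
#' @export
read_skeleton_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  voxel_size <- 1.0
  origin <- c(0, 0, 0)
  pts <- vector("list", length(lines))
  n <- 0L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      toks <- strsplit(sub("^#", "", ln), "[[:space:]]+")[[1]]
      toks <- toks[nzchar(toks)]
      if (length(toks) >= 2L && toks[1] == "voxel_size") voxel_size <- as.numeric(toks[2])
      if (length(toks) >= 4L && toks[1] == "origin") origin <- as.numeric(toks[2:4])
      next
    }
    toks <- strsplit(ln, "[,[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    val <- suppressWarnings(as.numeric(toks))
    if (length(val) != 3L || anyNA(val)) {
      stop(sprintf("malformed point on line %d of '%s': '%s'", i, path, lines[[i]]))
    }
    n <- n + 1L
    pts[[n]] <- val
  }
  if (n == 0L) stop(sprintf("empty skeleton: no points in '%s'", path))
  skeleton_cloud(do.call(rbind, pts[seq_len(n)]), voxel_size = voxel_size,
                 origin = origin, source = "text")
}

#' Write a skeleton point cloud to the plain-text XYZ dialect
#'
#' @param cloud A [skeleton_cloud()].
#' @param path Output file.
#' @export
write_skeleton_text <- function(cloud, path) {
  stopifnot(inherits(cloud, "skeleton_cloud"))
  hdr <- c(sprintf("#voxel_size %.10g", cloud$voxel_size),
           sprintf("#origin %.10g %.10g %.10g",
                   cloud$origin[1], cloud$origin[2], cloud$origin[3]))
  body <- apply(cloud$points, 1L, function(p) sprintf("%.10g %.10g %.10g", p[1], p[2], p[3]))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read helix-axis annotations
#'
#' Accepts either a JSON list `[{"id": ..., "p": [x,y,z], "q": [x,y,z]}, ...]`
#' or an equivalent 7-column text format (`id px py pz qx qy qz`, `#` comments
#' allowed). Coordinates are in Angstrom.
#'
#' @param path File to read.
#' @return List of [helix_axis()] objects.
#' @export
read_helices <- function(path) {
  raw <- readLines(path, warn = FALSE)
  first <- trimws(paste(raw, collapse = " "))
  if (startsWith(first, "[") || startsWith(first, "{")) {
    recs <- jsonlite::fromJSON(paste(raw, collapse = "\n"), simplifyDataFrame = FALSE,
                               simplifyVector = FALSE)
    if (!is.null(recs$id)) recs <- list(recs)
    helices <- lapply(recs, function(r) {
      helix_axis(r$id, unlist(r$p), unlist(r$q))
    })
  } else {
    helices <- list()
    for (i in seq_along(raw)) {
      ln <- trimws(raw[[i]])
      if (!nzchar(ln) || startsWith(ln, "#")) next
      toks <- strsplit(ln, "[,[:space:]]+")[[1]]
      toks <- toks[nzchar(toks)]
      if (length(toks) != 7L) {
        stop(sprintf("malformed helix on line %d of '%s' (need 7 columns)", i, path))
      }
      val <- suppressWarnings(as.numeric(toks[2:7]))
      if (anyNA(val)) stop(sprintf("malformed helix coordinates on line %d of '%s'", i, path))
      helices[[length(helices) + 1L]] <- helix_axis(toks[1], val[1:3], val[4:6])
    }
  }
  if (length(helices) == 0L) stop(sprintf("no helices in '%s'", path))
  helices
}

#' Write helix-axis annotations as JSON
#'
#' @param helices List of [helix_axis()] objects.
#' @param path Output file.
#' @export
write_helices <- function(helices, path) {
  recs <- lapply(helices, function(h) list(id = h$id, p = h$p, q = h$q))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

report_columns <- c("pair", "feasible", "expected", "measured", "diff",
                    "rel_err", "epsilon", "lcg_id")

#' Write a loop-length measurement report
#'
#' Serialises the per-endpoint-pair measurement table with columns
#' `pair, feasible, expected, measured, diff, rel_err, epsilon, lcg_id`
#' as TSV or JSON.
#'
#' @param reports Data frame of measurements (as in a `loop_length_fit`).
#' @param path Output file.
#' @param format `"tsv"` or `"json"`.
#' @export
write_report <- function(reports, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(reports)
  for (col in report_columns) if (is.null(df[[col]])) df[[col]] <- NA
  df <- df[, report_columns, drop = FALSE]
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
  } else {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Read back a measurement report written by [write_report()]
#'
#' @param path Report file.
#' @param format `"tsv"` or `"json"`.
#' @return Data frame with the report columns.
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                      na.strings = "NA")
  } else {
    as.data.frame(jsonlite::fromJSON(path))
  }
}
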