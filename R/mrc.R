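# Minimal MRC2014/CCP4 volume I/O, enough for skeleton maps: modes 0 (int8),
# 1 (int16) and 2 (float32), single volume, no extended header on write.

mrc_read_header <- function(raw_hdr) {
  machst <- raw_hdr[213:216]
  endian <- if (identical(as.integer(machst[1]), 0x11L)) "big" else "little"
  ints <- function(from, n) readBin(raw_hdr[(4 * (from - 1) + 1):(4 * (from - 1) + 4 * n)],
                                    "integer", n = n, size = 4L, endian = endian)
  flts <- function(from, n) readBin(raw_hdr[(4 * (from - 1) + 1):(4 * (from - 1) + 4 * n)],
                                    "numeric", n = n, size = 4L, endian = endian)
  list(
    n      = ints(1, 3),          # nx, ny, nz (columns, rows, sections)
    mode   = ints(4, 1),
    nstart = ints(5, 3),
    m      = ints(8, 3),          # sampling along cell axes
    cella  = flts(11, 3),
    axes   = ints(17, 3),         # mapc, mapr, maps
    nsymbt = ints(24, 1),
    origin = flts(50, 3),
    map    = rawToChar(raw_hdr[209:212]),
    endian = endian
  )
}

#' Read a skeleton point cloud from an MRC/CCP4 map
#'
#' Voxels with density strictly greater than `threshold` become skeleton
#' points; voxel indices are converted to Angstrom using the header voxel size
#' and origin (including any start offsets). Only isotropic maps are accepted.
#' Maps whose axis order is permuted (mapc/mapr/maps not 1,2,3) are rejected
#' unless `permissive = TRUE`, in which case the volume is normalised to
#' x-fastest order first.
#'
#' @param path MRC file.
#' @param threshold Density threshold; default 0 keeps any positive density.
#' @param permissive Normalise permuted axis order instead of rejecting it.
#' @return A [skeleton_cloud()] with `source = "map"`.
#' @export
read_skeleton_mrc <- function(path, threshold = 0.0, permissive = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw_hdr <- readBin(con, "raw", n = 1024L)
  if (length(raw_hdr) < 1024L) stop(sprintf("'%s' is not a readable MRC file", path))
  h <- mrc_read_header(raw_hdr)
  if (!identical(substr(h$map, 1, 3), "MAP")) {
    stop(sprintf("'%s' is not a readable MRC file (missing MAP magic)", path))
  }
  if (any(h$n <= 0) || !h$mode %in% c(0L, 1L, 2L)) {
    stop(sprintf("unsupported MRC layout in '%s' (mode %d)", path, h$mode))
  }
  voxel <- h$cella / h$m
  if (any(!is.finite(voxel)) || any(voxel <= 0)) stop("invalid cell dimensions in MRC header")
  if (max(voxel) - min(voxel) > 1e-3 * mean(voxel)) {
    stop(sprintf("anisotropic voxels (%s A) are not supported",
                 paste(sprintf("%.4g", voxel), collapse = ", ")))
  }
  if (h$nsymbt > 0) readBin(con, "raw", n = h$nsymbt)
  nvox <- prod(h$n)
  dat <- switch(as.character(h$mode),
    "0" = as.numeric(readBin(con, "integer", n = nvox, size = 1L, signed = TRUE,
                             endian = h$endian)),
    "1" = as.numeric(readBin(con, "integer", n = nvox, size = 2L, signed = TRUE,
                             endian = h$endian)),
    "2" = readBin(con, "numeric", n = nvox, size = 4L, endian = h$endian))
  if (length(dat) < nvox) stop(sprintf("truncated MRC data in '%s'", path))
  arr <- array(dat, dim = h$n)
  nstart <- h$nstart
  if (!identical(h$axes, 1:3)) {
    if (!permissive) {
      stop("MRC axis order is permuted (mapc/mapr/maps != 1,2,3); use permissive = TRUE")
    }
    perm <- match(1:3, h$axes)
    arr <- aperm(arr, perm)
    nstart <- nstart[perm]
  }
  idx <- which(arr > threshold, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty skeleton: no voxels above threshold")
  vs <- mean(voxel)
  origin <- h$origin + vs * nstart
  pts <- sweep((idx - 1) * vs, 2L, origin, `+`)
  skeleton_cloud(unname(pts), voxel_size = vs, origin = origin, source = "map")
}

#' Write a skeleton point cloud as an MRC map
#'
#' Points must lie on the cloud's cubic lattice (integer multiples of
#' `voxel_size` from the origin); each occupied voxel is written with density
#' 1.0 in a mode-2 (float32) MRC2014 volume.
#'
#' @param cloud A [skeleton_cloud()].
#' @param path Output file.
#' @export
write_skeleton_mrc <- function(cloud, path) {
  stopifnot(inherits(cloud, "skeleton_cloud"))
  vs <- cloud$voxel_size
  rel <- sweep(cloud$points, 2L, cloud$origin)
  idx <- round(rel / vs)
  if (max(abs(rel - idx * vs)) > 1e-6 * vs) {
    stop("points are not on the voxel lattice; cannot rasterise to MRC")
  }
  lo <- apply(idx, 2L, min)
  idx <- sweep(idx, 2L, lo)
  origin <- cloud$origin + vs * lo
  dims <- apply(idx, 2L, max) + 1
  arr <- array(0, dim = dims)
  arr[idx + 1] <- 1.0
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(dims)                      # nx ny nz
  wi(2L)                        # mode 2 = float32
  wi(c(0L, 0L, 0L))             # nstart
  wi(dims)                      # mx my mz
  wf(dims * vs)                 # cella
  wf(c(90, 90, 90))             # cellb
  wi(1:3)                       # mapc mapr maps
  wf(c(0, 1, sum(arr) / length(arr)))   # dmin dmax dmean
  wi(c(1L, 0L))                 # ispg, nsymbt
  wi(rep(0L, 25L))              # extra (words 26-49, incl. exttyp/nversion)
  wf(origin)                    # origin (words 50-52)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(arr))            # rms
  wi(0L)                        # nlabl
  writeBin(raw(800L), con)      # labels
  wf(as.vector(arr))
  invisible(path)
}
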