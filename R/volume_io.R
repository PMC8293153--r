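# MRC/CCP4 2014 volume I/O and the two voxel-grid containers used everywhere:
# a density map (real-valued grid + physical metadata + contour threshold) and
# a label map (non-negative integer grid; 0 = background).
#
# Grids are R arrays indexed [x, y, z] with x fastest. Because R arrays are
# column-major this is byte-identical to the MRC column/row/section layout, so
# volumes round-trip without any axis permutation.

#' Construct a density map
#'
#' A density map is a 3D real-valued grid with physical metadata: the voxel
#' spacing in Angstrom along each axis, the physical coordinate of grid index
#' (1,1,1), and an optional contour threshold. Voxels with density strictly
#' above the threshold form the foreground that all segmentation operates on.
#'
#' @param grid 3D numeric array, indexed `[x, y, z]`, each axis of length >= 1.
#' @param voxel_size Voxel edge length in Angstrom; length 1 (isotropic) or 3.
#' @param origin Physical coordinate of the first voxel, length 3 (Angstrom).
#' @param threshold Contour level; `NA` means "not yet set" (see
#'   [estimate_threshold()]).
#' @return An object of class `density_map`.
#' @seealso [read_density()], [foreground_mask()]
#' @export
#' @examples
#' m <- density_map(array(rnorm(64), c(4, 4, 4)), voxel_size = 1.5)
#' dim(m$grid)
density_map <- function(grid, voxel_size = 1, origin = c(0, 0, 0),
                        threshold = NA_real_) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("`grid` must be a 3D array", call. = FALSE)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0))
    stop("`voxel_size` components must be strictly positive", call. = FALSE)
  structure(
    list(grid = grid, voxel_size = voxel_size,
         origin = rep_len(as.numeric(origin), 3L),
         threshold = as.numeric(threshold)[1L]),
    class = "density_map")
}

#' Construct a label map
#'
#' A label map assigns each voxel a non-negative integer segment identifier;
#' 0 is reserved for background. It is the universal representation of a
#' segmentation and of ground truth throughout the package.
#'
#' @param labels 3D array of non-negative integers.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array", call. = FALSE)
  if (anyNA(labels) || any(labels < 0))
    stop("labels must be non-negative integers (0 = background)",
         call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels), class = "label_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<density_map> %d x %d x %d voxels, %.3g A/voxel\n",
              d[1], d[2], d[3], x$voxel_size[1]))
  cat(sprintf("  density range [%.4g, %.4g], threshold %s\n",
              min(x$grid), max(x$grid),
              if (is.na(x$threshold)) "unset" else format(x$threshold)))
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_map> %d x %d x %d voxels, %d segment(s), %d foreground voxel(s)\n",
              d[1], d[2], d[3], n_segments(x), sum(x$labels > 0L)))
  invisible(x)
}

#' Number of distinct positive labels in a label map
#' @param labels A `label_map`.
#' @return Integer count of segments.
#' @export
n_segments <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  length(setdiff(unique(as.vector(labels$labels)), 0L))
}

# ---- MRC 2014 binary format ------------------------------------------------

.mrc_read_header <- function(con) {
  ints <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  cell <- readBin(con, "double", n = 6L, size = 4L, endian = "little")
  mapcrs <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  dstats <- readBin(con, "double", n = 3L, size = 4L, endian = "little")
  ispg_nsymbt <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  readBin(con, "raw", n = 100L)                       # EXTRA (words 26-49)
  orig <- readBin(con, "double", n = 3L, size = 4L, endian = "little")
  map_tag <- readChar(con, 4L, useBytes = TRUE)
  readBin(con, "raw", n = 4L)                         # MACHST
  rms <- readBin(con, "double", n = 1L, size = 4L, endian = "little")
  readBin(con, "raw", n = 4L + 800L)                  # NLABL + labels
  list(nxyz = ints[1:3], mode = ints[4], start = ints[5:7], mxyz = ints[8:10],
       cella = cell[1:3], mapcrs = mapcrs, dstats = dstats,
       nsymbt = ispg_nsymbt[2], origin = orig, map_tag = map_tag, rms = rms)
}

.mrc_read <- function(path) {
  size <- file.info(path)$size
  if (is.na(size) || size < 1024)
    stop(sprintf("'%s' is not a readable MRC volume (too small)", path),
         call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- .mrc_read_header(con)
  n <- prod(h$nxyz)
  if (any(h$nxyz < 1L) || n <= 0)
    stop(sprintf("'%s': inconsistent MRC header dimensions", path),
         call. = FALSE)
  bytes <- switch(as.character(h$mode),
                  "0" = 1L, "1" = 2L, "2" = 4L, "6" = 2L,
                  stop(sprintf("'%s': unsupported MRC mode %d", path, h$mode),
                       call. = FALSE))
  if (size < 1024 + h$nsymbt + as.numeric(n) * bytes)
    stop(sprintf("'%s': truncated MRC file", path), call. = FALSE)
  if (h$nsymbt > 0) readBin(con, "raw", n = h$nsymbt)
  vals <- switch(as.character(h$mode),
    "0" = readBin(con, "integer", n = n, size = 1L, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "double", n = n, size = 4L, endian = "little"),
    "6" = readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                  endian = "little"))
  if (length(vals) != n)
    stop(sprintf("'%s': truncated MRC data block", path), call. = FALSE)
  h$grid <- array(vals, dim = h$nxyz)
  h
}

.mrc_write <- function(grid, path, voxel_size, origin, mode = 2L) {
  d <- dim(grid)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d, mode, 0L, 0L, 0L, d)), con, size = 4L,
           endian = "little")
  writeBin(as.numeric(c(d * voxel_size, 90, 90, 90)), con, size = 4L,
           endian = "little")
  writeBin(c(1L, 2L, 3L), con, size = 4L, endian = "little")
  writeBin(as.numeric(c(min(grid), max(grid), mean(grid))), con, size = 4L,
           endian = "little")
  writeBin(c(1L, 0L), con, size = 4L, endian = "little")     # ISPG, NSYMBT
  writeBin(raw(100L), con)                                   # EXTRA
  writeBin(as.numeric(origin), con, size = 4L, endian = "little")
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)           # MACHST (LE)
  writeBin(stats::sd(as.vector(grid)), con, size = 4L, endian = "little")
  writeBin(0L, con, size = 4L, endian = "little")            # NLABL
  writeBin(raw(800L), con)
  writeBin(as.numeric(grid), con, size = 4L, endian = "little")
  invisible(NULL)
}

#' Read a density map from an MRC/CCP4 file
#'
#' @param path Path to an MRC 2014 volume (mode 0/1/2/6).
#' @param threshold Optional contour level to attach to the map.
#' @return A [density_map()].
#' @export
read_density <- function(path, threshold = NA_real_) {
  h <- .mrc_read(path)
  vx <- ifelse(h$mxyz > 0, h$cella / h$mxyz, 1)
  vx[!is.finite(vx) | vx <= 0] <- 1
  density_map(h$grid, voxel_size = vx, origin = h$origin,
              threshold = threshold)
}

#' Write a density map to an MRC file (mode 2, float32)
#'
#' @param map A [density_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_density <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  .mrc_write(map$grid, path, map$voxel_size, map$origin, mode = 2L)
  invisible(path)
}

#' Read / write label volumes as MRC
#'
#' Label volumes are stored as MRC mode 2 (float32) with integral values —
#' classic MRC has no 32-bit integer mode and watershed output can exceed the
#' int16 range. Values are rounded back to integers on read.
#'
#' @param path Path to the label volume.
#' @return `read_labels()` returns a [label_map()].
#' @export
read_labels <- function(path) {
  h <- .mrc_read(path)
  lab <- round(h$grid)
  if (any(lab < 0))
    stop(sprintf("'%s': label volume contains negative values", path),
         call. = FALSE)
  label_map(array(as.integer(lab), dim = dim(h$grid)))
}

#' @rdname read_labels
#' @param labels A [label_map()].
#' @param voxel_size,origin Physical metadata to record in the header.
#' @export
write_labels <- function(labels, path, voxel_size = 1, origin = c(0, 0, 0)) {
  stopifnot(inherits(labels, "label_map"))
  .mrc_write(labels$labels, path, rep_len(voxel_size, 3L), origin, mode = 2L)
  invisible(path)
}

#' Estimate a contour threshold by Otsu's method
#'
#' Used when no author-recommended contour level is available: the threshold
#' maximizing between-class variance over a 256-bin histogram of the non-zero
#' densities separates foreground envelope from solvent background.
#'
#' @param map A [density_map()].
#' @param nbins Histogram resolution.
#' @return The estimated threshold (numeric scalar).
#' @export
estimate_threshold <- function(map, nbins = 256L) {
  stopifnot(inherits(map, "density_map"))
  v <- as.vector(map$grid)
  v <- v[v != 0]
  if (length(v) < 2L || min(v) == max(v))
    stop("cannot estimate a threshold: degenerate density distribution",
         call. = FALSE)
  br <- seq(min(v), max(v), length.out = nbins + 1L)
  counts <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w1 <- cumsum(counts)
  w2 <- sum(counts) - w1
  m1 <- cumsum(counts * mids) / pmax(w1, 1)
  m2 <- (sum(counts * mids) - cumsum(counts * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (m1 - m2)^2
  between[w1 == 0 | w2 == 0] <- -Inf
  mids[which.max(between)]
}

#' Foreground mask of a density map
#'
#' The foreground is the set of voxels with density strictly above the contour
#' threshold; every segmentation operation in the package acts only on this
#' set. If the map has no threshold set one is estimated with
#' [estimate_threshold()].
#'
#' @param map A [density_map()].
#' @return A 3D logical array of the same shape as the grid.
#' @export
foreground_mask <- function(map) {
  stopifnot(inherits(map, "density_map"))
  thr <- map$threshold
  if (is.na(thr)) thr <- estimate_threshold(map)
  map$grid > thr
}

#' Canonicalize segment labels
#'
#' Renumbers the positive labels to the contiguous range `1..K` (in increasing
#' order of the original values) without changing which voxels share a label;
#' background voxels are untouched.
#'
#' @param labels A [label_map()].
#' @return A [label_map()] with labels exactly `{0, 1, ..., K}`.
#' @export
canonicalize_labels <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  lab <- labels$labels
  pos <- sort(setdiff(unique(as.vector(lab)), 0L))
  if (length(pos) == 0L) return(labels)
  lut <- integer(max(pos) + 1L)
  lut[pos + 1L] <- seq_along(pos)
  out <- array(lut[lab + 1L], dim = dim(lab))
  label_map(out)
}
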