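# Structural feature encoding of a segmentation: one global component (the
# segment count) plus, for each of up to 60 segments, its volume proportion
# and its Euler-Poincare characteristic. 1 + 60 * 2 = 121 components; the
# fixed length is what the segmentation-quality classifier consumes.

#' Number of components in a feature vector
#' @export
FEATURE_LENGTH <- 121L

#' Maximum number of segments encoded in a feature vector
#' @export
MAX_SEGMENTS <- 60L

# OR-accumulate the mask over 0/1 shifts along the axes in `vary` and count
# cells. Vertices vary all three axes, edges two, faces one, cubes none.
.cell_count <- function(m, vary) {
  d <- dim(m)
  nd <- d + as.integer(1:3 %in% vary)
  A <- array(FALSE, nd)
  offs <- expand.grid(lapply(1:3, function(a) if (a %in% vary) 0:1 else 0L))
  for (r in seq_len(nrow(offs))) {
    o <- as.integer(offs[r, ])
    i1 <- seq_len(d[1]) + o[1]
    i2 <- seq_len(d[2]) + o[2]
    i3 <- seq_len(d[3]) + o[3]
    A[i1, i2, i3] <- A[i1, i2, i3, drop = FALSE] | m
  }
  sum(A)
}

#' Euler-Poincare characteristic of a voxel set
#'
#' Treats each voxel as a closed unit cube and computes
#' `chi = V - E + F - C` over the resulting cubical complex (vertices minus
#' edges plus square faces minus cubes) by local cell counting. Under this
#' convention a solid blob has `chi = 1`, each tunnel (handle) subtracts 1,
#' and each enclosed cavity adds 1. The value is translation invariant, which
#' is what makes it usable as a shape descriptor for protein segments.
#'
#' @param x A 3D logical (or 0/1) array, or an `n x 3` integer matrix of voxel
#'   coordinates.
#' @return Integer Euler characteristic.
#' @export
#' @examples
#' euler_characteristic(array(TRUE, c(1, 1, 1)))  # single cube: 1
euler_characteristic <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 3L || nrow(x) == 0L)
      stop("coordinate input must be a non-empty n x 3 matrix", call. = FALSE)
    x <- sweep(x, 2L, apply(x, 2L, min) - 1L)      # compact to positive range
    m <- array(FALSE, apply(x, 2L, max))
    m[x] <- TRUE
  } else {
    stopifnot(is.array(x), length(dim(x)) == 3L)
    m <- x != 0
  }
  if (!any(m)) stop("empty voxel set has no Euler characteristic",
                    call. = FALSE)
  V <- .cell_count(m, c(1, 2, 3))
  E <- .cell_count(m, c(2, 3)) + .cell_count(m, c(1, 3)) +
       .cell_count(m, c(1, 2))
  F <- .cell_count(m, 3) + .cell_count(m, 2) + .cell_count(m, 1)
  as.integer(V - E + F - sum(m))
}

#' Per-segment volumes of a segmentation
#'
#' @param labels A [label_map()] with at least one positive voxel.
#' @return A tibble with columns `label`, `voxels` and `proportion`
#'   (fraction of the total foreground volume; proportions sum to 1).
#' @export
segment_volumes <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  lab <- labels$labels
  fg <- lab[lab > 0L]
  if (length(fg) == 0L)
    stop("empty foreground: no segments to measure", call. = FALSE)
  counts <- tabulate(fg)
  keep <- which(counts > 0L)
  tibble(label = keep, voxels = counts[keep],
         proportion = counts[keep] / length(fg))
}

#' Encode a segmentation as a 121-component feature vector
#'
#' Component 1 is the segment count (capped at 60). Segments are sorted by
#' decreasing volume (ties by label) — making the encoding invariant to label
#' permutation — and the i-th kept segment fills components `2i` and `2i + 1`
#' with its volume proportion and Euler characteristic. Unused components are
#' zero. When more than 60 segments are present, the 60 largest are encoded
#' and component 1 reports the capped value.
#'
#' @param labels A [label_map()] with non-empty foreground.
#' @return A numeric vector of length 121.
#' @export
encode_features <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  vols <- segment_volumes(labels)
  ord <- order(-vols$voxels, vols$label)
  vols <- vols[ord, ]
  k <- min(nrow(vols), MAX_SEGMENTS)
  x <- numeric(FEATURE_LENGTH)
  x[1L] <- k
  lab <- labels$labels
  d <- dim(lab)
  for (i in seq_len(k)) {
    id <- vols$label[i]
    idx <- which(lab == id, arr.ind = FALSE)
    ai <- arrayInd(idx, d)
    rng <- apply(ai, 2L, range)
    sub <- lab[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3],
               drop = FALSE]
    if (!is.array(sub)) sub <- array(sub, rng[2, ] - rng[1, ] + 1L)
    x[2L * i] <- vols$proportion[i]
    x[2L * i + 1L] <- euler_characteristic(sub == id)
  }
  x
}
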