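# Independent oracles used across the suite. These deliberately recompute
# quantities by brute force / enumeration, never through the package's own
# code paths.

# Euler characteristic by explicit cell enumeration. In doubled coordinates
# the closed unit cube of voxel v covers the 27 lattice points 2v-2..2v per
# axis; each point is one cell of the cubical complex, and its dimension is
# the number of odd coordinates (vertex 0, edge 1, face 2, cube 3). So
# chi = sum over distinct cells of (-1)^(number of odd coordinates).
oracle_euler <- function(mask) {
  idx <- which(mask)
  stopifnot(length(idx) > 0L)
  co <- arrayInd(idx, dim(mask))
  off <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  cells <- NULL
  for (r in seq_len(nrow(co))) {
    base <- 2L * co[r, ] - 2L
    cells <- rbind(cells, sweep(off, 2L, base, `+`))
  }
  cells <- unique(cells)
  n_odd <- rowSums(cells %% 2L == 1L)
  sum((-1L)^n_odd)
}

# all permutations of 1..n (n small)
oracle_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- oracle_perms(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    left <- sub[, seq_len(k - 1L), drop = FALSE]
    right <- if (k <= n - 1L) sub[, k:(n - 1L), drop = FALSE]
             else sub[, 0, drop = FALSE]
    out <- rbind(out, cbind(left, n, right))
  }
  unname(out)
}

# matched IoU ("all" mode) by exhaustive search over label permutations
oracle_matched_iou_all <- function(pred, truth) {
  p <- as.vector(pred$labels)
  t <- as.vector(truth$labels)
  pl <- sort(setdiff(unique(p), 0L))
  tl <- sort(setdiff(unique(t), 0L))
  if (length(pl) == 0L || length(tl) == 0L) return(0)
  iou <- matrix(0, length(pl), length(tl))
  for (i in seq_along(pl)) for (j in seq_along(tl)) {
    a <- p == pl[i]
    b <- t == tl[j]
    iou[i, j] <- sum(a & b) / sum(a | b)
  }
  n <- max(length(pl), length(tl))
  perms <- oracle_perms(n)
  best <- 0
  for (r in seq_len(nrow(perms))) {
    perm <- perms[r, ]
    tot <- 0
    for (i in seq_along(pl))
      if (perm[i] <= length(tl)) tot <- tot + iou[i, perm[i]]
    best <- max(best, tot)
  }
  best / n
}

# AUC by the Mann-Whitney rank statistic
oracle_auc <- function(scores, labels01) {
  n1 <- sum(labels01 == 1)
  n0 <- sum(labels01 == 0)
  r <- rank(scores)
  (sum(r[labels01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
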